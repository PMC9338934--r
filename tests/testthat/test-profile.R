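mk_runs <- function(motif, tract) {
  data.frame(canonical_motif = motif, tract_length = as.integer(tract))
}

mk_stats <- function(lens) library_stats(lens)

test_that("profiles count every run and score by the printed formula", {
  # one AGC x 50 read among n = 10: counts["AGC"][150] == 1
  stats <- mk_stats(rep(150L, 10))
  prof <- build_profile(mk_runs("AGC", 150), stats, "s1")
  expect_equal(prof$library_size, 10L)
  expect_equal(prof$counts,
               data.frame(motif = "AGC", tract_length = 150L, count = 1L))

  # two distinct runs in one read increment two motif vectors
  prof2 <- build_profile(mk_runs(c("AT", "CG"), c(20, 30)), stats, "s2")
  expect_equal(nrow(prof2$counts), 2L)
  expect_equal(sum(prof2$counts$count), 2L)

  # period-7 motifs are dropped by the reporting cap
  prof3 <- build_profile(mk_runs("AACCGGT", 140), stats, "s3")
  expect_equal(nrow(prof3$counts), 0L)

  # n = 1000, j = 150 (i = 112), v_150 = 2 -> s = 2 * 150 / 1000 = 0.3
  stats2 <- mk_stats(rep(150L, 1000))
  prof4 <- build_profile(mk_runs(c("AGC", "AGC"), c(150, 150)), stats2, "s4")
  sv <- information_scores(prof4)
  expect_equal(unname(sv$scores["AGC"]), 0.3)
  expect_equal(unname(sv$window), c(112L, 150L))

  # tract 100 with i = 112 contributes nothing
  prof5 <- build_profile(mk_runs("AAG", 100), stats2, "s5")
  expect_equal(unname(information_scores(prof5)$scores["AAG"]), 0)

  # empty counts -> empty scores
  prof6 <- build_profile(mk_runs(character(), integer()), stats2, "s6")
  expect_length(information_scores(prof6)$scores, 0L)
})

test_that("score window validation", {
  prof <- build_profile(mk_runs("AGC", 150), mk_stats(rep(150L, 10)), "s")
  expect_error(information_scores(prof, i = 120, j = 100),
               class = "strsift_config_error")
  expect_error(information_scores(prof, i = 1, j = 200),
               class = "strsift_config_error")
  # explicit window overrides the default: one tract of 150 among n = 10
  sv <- information_scores(prof, i = 1, j = 150)
  expect_equal(unname(sv$scores["AGC"]), 15)
})

test_that("scores are linear in reads and invariant under duplication", {
  # two halves of one sample: v adds, and s combines as the weighted mean
  runs1 <- mk_runs(c("AGC", "AGC"), c(150, 120))
  runs2 <- mk_runs(c("AGC", "AAG"), c(130, 140))
  s1 <- mk_stats(rep(150L, 400)); s2 <- mk_stats(rep(150L, 600))
  p1 <- build_profile(runs1, s1, "a")
  p2 <- build_profile(runs2, s2, "a")
  p12 <- build_profile(rbind(runs1, runs2), mk_stats(rep(150L, 1000)), "a")
  sc1 <- information_scores(p1)$scores
  sc2 <- information_scores(p2)$scores
  sc12 <- information_scores(p12)$scores
  for (m in names(sc12)) {
    v1 <- if (m %in% names(sc1)) sc1[[m]] else 0
    v2 <- if (m %in% names(sc2)) sc2[[m]] else 0
    expect_equal(sc12[[m]], (400 * v1 + 600 * v2) / 1000)
  }

  # duplicating every read doubles v and leaves s unchanged
  pd <- build_profile(rbind(runs1, runs1), mk_stats(rep(150L, 800)), "a")
  expect_equal(information_scores(pd)$scores,
               information_scores(build_profile(runs1, mk_stats(rep(150L, 400)),
                                                "a"))$scores)
  expect_equal(pd$counts$count, c(1L, 1L) * 2L)
})

test_that("s_m is non-decreasing in in-window counts", {
  base <- mk_runs("AGC", 150)
  more <- rbind(base, mk_runs("AGC", 140))
  n <- mk_stats(rep(150L, 100))
  expect_gt(information_scores(build_profile(more, n, "x"))$scores["AGC"],
            information_scores(build_profile(base, n, "x"))$scores["AGC"])
})

test_that("cohort assembly fills absent motifs with zero and validates input", {
  sv <- function(id, scores) {
    structure(list(sample_id = id, scores = scores,
                   window = c(i = 112L, j = 150L)),
              class = "score_vector")
  }
  labels <- c(a = "case", b = "control", c = "control")
  coh <- assemble_cohort(list(sv("a", c(AGC = 0.3)),
                              sv("b", c(AGC = 0.1, AAG = 0.2)),
                              sv("c", c(AAG = 0.05))), labels)
  expect_equal(dim(coh$scores), c(3L, 2L))
  expect_equal(coh$scores["a", "AAG"], 0)
  expect_equal(coh$scores["c", "AGC"], 0)

  expect_error(assemble_cohort(list(sv("a", c(AGC = 1)),
                                    sv("a", c(AGC = 2))), labels),
               class = "strsift_config_error")
  bad <- sv("c", c(AAG = 1)); bad$window <- c(i = 75L, j = 100L)
  expect_error(assemble_cohort(list(sv("a", c(AGC = 1)), bad), labels),
               "common read length")
})

test_that("profiles survive a TSV round trip", {
  prof <- build_profile(mk_runs(c("AGC", "AAG"), c(150, 120)),
                        mk_stats(rep(150L, 50)), "sampleX")
  path <- tempfile(fileext = ".tsv")
  write_profile(prof, path)
  back <- read_profile(path)
  expect_equal(back$sample_id, "sampleX")
  expect_equal(back$library_size, 50L)
  expect_equal(back$read_length, 150L)
  expect_equal(back$counts, prof$counts)
})
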