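test_that("background reads follow the configured distribution", {
  cfg <- sim_config(read_length = 100L)
  reads <- background_reads(cfg, 5000, seed = 1)
  expect_equal(nchar(reads), rep(100L, 5000))
  freq <- table(strsplit(paste(reads, collapse = ""), "")[[1]]) / 5e5
  expect_true(all(abs(freq - 0.25) < 0.01))

  # degenerate distribution
  cfg1 <- sim_config(background = "custom", probs = c(1, 0, 0, 0),
                     read_length = 20L)
  expect_equal(background_reads(cfg1, 2, seed = 1),
               rep(strrep("A", 20), 2))

  # determinism
  expect_identical(background_reads(cfg, 50, seed = 9),
                   background_reads(cfg, 50, seed = 9))
})

test_that("repeat reads embed the tract and label by the 45-nt rule", {
  cfg <- sim_config(read_length = 150L)
  r <- repeat_read(cfg, "AGC", 150, offset = 0, seed = 2)
  expect_equal(r$sequence, strrep("AGC", 50))
  expect_true(r$label)

  expect_false(repeat_read(cfg, "AGC", 44, seed = 2)$label)
  expect_true(repeat_read(cfg, "AGC", 45, seed = 2)$label)

  r2 <- repeat_read(cfg, "TTC", 60, offset = 30, seed = 3)
  expect_equal(substr(r2$sequence, 31, 90), substr(strrep("TTC", 20), 1, 60))

  expect_error(repeat_read(cfg, "AGC", 200), class = "strsift_config_error")
  expect_error(repeat_read(cfg, "AGC", 30, offset = 140),
               class = "strsift_config_error")
})

test_that("substitution errors occur at the configured rate", {
  cfg <- sim_config(read_length = 100L, error_rate = 0.01)
  template <- strrep("ACGT", 25)
  reads <- strsift:::apply_errors_str(rep(template, 10000), 0.01)
  mism <- vapply(reads, function(r) {
    sum(strsplit(r, "")[[1]] != strsplit(template, "")[[1]])
  }, numeric(1))
  expect_lt(abs(mean(mism) / 100 - 0.01), 0.001)
})

test_that("motif impurity alters single copies at the configured rate", {
  cfg <- sim_config(read_length = 150L, motif_change_prob = 0.5)
  set.seed(5)
  mism <- unlist(lapply(1:40, function(i) {
    r <- strsift:::repeat_reads_vec(cfg, motif_lens = 3L, repeat_nts = 150L,
                                    offsets = 0L, motifs = "AGC")
    copies <- substring(r, seq(1, 148, 3), seq(3, 150, 3))
    vapply(copies, function(cp) {
      sum(strsplit(cp, "")[[1]] != c("A", "G", "C"))
    }, numeric(1))
  }))
  expect_true(all(mism <= 1))             # at most one substitution per copy
  expect_gt(mean(mism > 0), 0.4)          # ~half the copies altered
  expect_lt(mean(mism > 0), 0.6)
  expect_equal(sim_config(motif_change_prob = 0)$motif_change_prob, 0)
  expect_error(sim_config(motif_change_prob = 1),
               class = "strsift_config_error")
})

test_that("error-free repeat reads are recovered exactly by find_runs", {
  cfg <- sim_config(read_length = 150L)
  set.seed(6)
  for (rep in 1:40) {
    mlen <- sample(1:6, 1)
    rn <- sample((2 * mlen + 9):150, 1)
    rd <- strsift:::repeat_reads_vec(cfg, motif_lens = mlen, repeat_nts = rn)
    runs <- find_runs(rd, min_tract = 9)
    expect_true(any(runs$tract_length >= rn),
                info = paste("mlen", mlen, "rn", rn, "read", rd))
  }
})

test_that("simulated loci have clean flanks and exact geometry", {
  cfg <- sim_config(read_length = 150L)
  locus <- simulated_locus(cfg, "AGC", n_copies = 50, seed = 8)
  expect_equal(nchar(locus$sequence), 2500 + 150 + 2500)
  expect_equal(locus$insert_start, 2500L)
  expect_equal(nrow(find_runs(locus$flank5, min_tract = 15)), 0L)
  expect_equal(nrow(find_runs(locus$flank3, min_tract = 15)), 0L)
  expect_equal(substr(locus$sequence, 2501, 2650), strrep("AGC", 50))
})

test_that("locus read sampling matches depth arithmetic and labelling", {
  cfg <- sim_config(read_length = 150L)
  locus <- simulated_locus(cfg, "AGC", n_copies = 50, seed = 8)
  lr <- simulate_locus_reads(locus, depth = 30, config = cfg, seed = 9)
  expect_length(lr$sequence, round(30 * 5150 / 150))  # 1030 reads
  # labelling: overlap >= 45 nt with the tract
  t0 <- locus$insert_start; t1 <- t0 + locus$tract_length
  overlap <- pmax(0, pmin(lr$start + 150, t1) - pmax(lr$start, t0))
  expect_identical(lr$label, overlap >= 45)
  # reads fully inside the tract are informative
  inside <- lr$start >= t0 & lr$start + 150 <= t1
  expect_true(all(lr$label[inside]))
})

test_that("cohort fixtures are reproducible byte for byte", {
  cfg <- sim_config(read_length = 100L)
  d1 <- tempfile("c1"); d2 <- tempfile("c2")
  m1 <- simulate_cohort(1, 1, reads_per_sample = 500, config = cfg,
                        dir = d1, depth = 5, flank_length = 300,
                        seed = 12)
  m2 <- simulate_cohort(1, 1, reads_per_sample = 500, config = cfg,
                        dir = d2, depth = 5, flank_length = 300,
                        seed = 12)
  for (f in c("case_01.fasta", "control_01.fasta")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
  man <- read_manifest(m1)
  expect_equal(man$label, c("case", "control"))
})

test_that("classifier evaluation returns coherent confusion metrics", {
  cfg <- sim_config(read_length = 150L)
  tab <- default_thresholds()
  ev <- evaluate_classifier(cfg, tab, n_per_class = 1000,
                            negatives = "background", seed = 13)
  expect_equal(ev$tp + ev$fn, 1000)
  expect_equal(ev$tn + ev$fp, 1000)
  expect_gte(ev$sensitivity, 0.99)
  expect_gte(ev$specificity, 0.99)
  expect_error(evaluate_classifier(cfg, tab, 0),
               class = "strsift_config_error")
})
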