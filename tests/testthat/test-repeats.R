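test_that("find_runs recovers forced examples exactly", {
  r <- find_runs("ACGACGACG", min_tract = 2)
  expect_equal(nrow(r), 1L)
  expect_equal(r$start, 0L); expect_equal(r$end, 9L)
  expect_equal(r$period, 3L); expect_equal(r$motif, "ACG")
  expect_equal(r$tract_length, 9L)

  r <- find_runs("AAAA", min_tract = 2)
  expect_equal(nrow(r), 1L)
  expect_equal(r[, c("start", "end", "period")],
               data.frame(start = 0L, end = 4L, period = 1L))

  r <- find_runs("ATATATCGCGCG", min_tract = 2)
  expect_equal(r[, c("start", "end", "period")],
               data.frame(start = c(0L, 6L), end = c(6L, 12L),
                          period = c(2L, 2L)))
  expect_equal(r$motif, c("AT", "CG"))

  # fractional trailing copy extends the tract
  r <- find_runs("AGCAGCA", min_tract = 2)
  expect_equal(r$tract_length, 7L)
  expect_equal(r$period, 3L)
})

test_that("positions holding N belong to no run", {
  r <- find_runs("AAANAAA", min_tract = 2)
  expect_equal(r[, c("start", "end")], data.frame(start = c(0L, 4L),
                                                  end = c(3L, 7L)))
  expect_equal(nrow(find_runs("ANANANAN", min_tract = 2)), 0L)
})

test_that("find_runs agrees with the brute-force oracle on random strings", {
  set.seed(97)
  for (rep in 1:300) {
    len <- sample(5:40, 1)
    s <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
               collapse = "")
    got <- find_runs(s, min_tract = 2)
    want <- oracle_runs(s, min_tract = 2)
    expect_identical(runs_key(got), runs_key(want),
                     info = paste("string:", s))
    expect_lte(nrow(got), nchar(s))  # runs theorem bound
  }
  # low-alphabet strings are the repeat-dense stress case
  for (rep in 1:200) {
    len <- sample(4:25, 1)
    s <- paste(sample(c("A", "C"), len, replace = TRUE), collapse = "")
    expect_identical(runs_key(find_runs(s, min_tract = 2)),
                     runs_key(oracle_runs(s, min_tract = 2)),
                     info = paste("string:", s))
  }
})

test_that("min_tract filters short runs", {
  r <- find_runs("AAAATTTTTTT", min_tract = 5)
  expect_equal(r$motif, "T")
  expect_error(find_runs("AAAA", min_tract = 1),
               class = "strsift_config_error")
})

test_that("canonical motifs match the reporting convention", {
  expect_equal(canonical_motif("CTG"), "AGC")  # CAG/CTG class
  expect_equal(canonical_motif("CAG"), "AGC")
  expect_equal(canonical_motif("GAA"), "AAG")  # FRDA GAA class
  expect_equal(canonical_motif("TTC"), "AAG")
  expect_equal(canonical_motif("ATAT"), "AT")  # primitive-root reduction
  expect_equal(canonical_motif("CGG"), canonical_motif("CCG"))
})

test_that("canonicalisation is idempotent and rotation/revcomp invariant", {
  set.seed(31)
  for (k in 1:6) {
    motifs <- unique(random_dna(30, k))
    canon <- canonical_motif(motifs)
    expect_identical(canonical_motif(canon), canon)
    for (i in seq_along(motifs)) {
      m <- motifs[i]
      for (rot in oracle_rotations(m))
        expect_identical(canonical_motif(rot), canon[i])
      expect_identical(canonical_motif(oracle_revcomp(m)), canon[i])
    }
  }
  expect_error(canonical_motif("AGN"), class = "strsift_config_error")
})

test_that("motif class enumeration matches the orbit oracle", {
  expect_identical(enumerate_motif_classes(1, 1), c("A", "C"))
  for (k in 1:5) {
    expect_identical(enumerate_motif_classes(k, k), oracle_motif_classes(k))
  }
  expect_error(enumerate_motif_classes(3, 7), class = "strsift_config_error")
})

test_that("scan_read short-circuits on high-complexity reads", {
  tab <- default_thresholds()
  set.seed(41)
  high <- random_dna(1, 150)
  expect_equal(nrow(scan_read(high, tab)), 0L)

  rep_read <- strrep("AGC", 50)
  r <- scan_read(rep_read, tab)
  expect_equal(nrow(r), 1L)
  expect_equal(r$canonical_motif, "AGC")
  expect_equal(r$tract_length, 150L)

  # random prefix + AAG tract: run confined to the suffix
  set.seed(42)
  prefix <- random_dna(1, 75)
  s <- paste0(prefix, strrep("AAG", 25))
  r <- scan_read(s, tab)
  aag <- r[r$canonical_motif == "AAG" & r$tract_length == 75L, ]
  expect_equal(nrow(aag), 1L)
  expect_equal(aag$start, 75L)
  expect_equal(aag$end, 150L)
  expect_identical(runs_key(r[, c("start", "end", "period")]),
                   runs_key(oracle_runs(s, min_tract = 9)))
})

test_that("scan_reads processes candidates only and tags read ids", {
  tab <- default_thresholds()
  set.seed(43)
  fa <- tempfile(fileext = ".fa")
  seqs <- c(bg1 = random_dna(1, 150), rep1 = strrep("TTC", 50),
            bg2 = random_dna(1, 150))
  write_reads_fasta(seqs, fa)
  rs <- stream_reads(fa)
  runs <- scan_reads(rs, tab)
  expect_equal(attr(runs, "n_candidates"), 1L)
  expect_true(all(runs$read_id == "rep1"))
  expect_true("AAG" %in% runs$canonical_motif)
})
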