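#' Simulation configuration
#'
#' Defines the background nucleotide distribution, read length and error
#' model used by every generator. Background presets are single-nucleotide
#' frequency vectors: `"uniform"` (each base 1/4) and three named genomic
#' compositions - `"human"` (~41% GC), `"gc_rich"` (a GC-rich
#' actinobacterial genome, ~72% GC) and `"at_rich"` (AT-rich protozoan
#' intergenic sequence, ~13% GC). Sequencing error is a constant per-base
#' substitution probability (no indels); repeat impurity is controlled
#' separately by `motif_change_prob`, the probability that any one motif
#' copy in a simulated tract carries a single random substitution.
#'
#' @param background One of `"uniform"`, `"human"`, `"gc_rich"`,
#'   `"at_rich"`, `"custom"`.
#' @param probs Numeric length-4 vector (p_A, p_C, p_G, p_T) summing to 1;
#'   required for `"custom"`, otherwise taken from the preset.
#' @param read_length Read length in nt (default 150).
#' @param error_rate Per-base substitution probability in [0, 1).
#' @param motif_change_prob Per-copy motif alteration probability in
#'   [0, 1).
#' @param seed Default seed for generators using this config.
#' @return A `sim_config` list.
#' @export
sim_config <- function(background = c("uniform", "human", "gc_rich",
                                      "at_rich", "custom"),
                       probs = NULL, read_length = 150L, error_rate = 0,
                       motif_change_prob = 0, seed = NULL) {
  background <- match.arg(background)
  presets <- list(
    uniform = c(0.25, 0.25, 0.25, 0.25),
    human   = c(0.295, 0.205, 0.205, 0.295),
    gc_rich = c(0.14, 0.36, 0.36, 0.14),
    at_rich = c(0.435, 0.065, 0.065, 0.435)
  )
  if (background == "custom") {
    if (is.null(probs)) stop_config("custom background requires probs")
  } else {
    probs <- probs %||% presets[[background]]
  }
  if (length(probs) != 4L || abs(sum(probs) - 1) > 1e-9 || any(probs < 0))
    stop_config("probs must be 4 non-negative values summing to 1")
  if (error_rate < 0 || error_rate >= 1)
    stop_config("error_rate must lie in [0, 1)")
  if (motif_change_prob < 0 || motif_change_prob >= 1)
    stop_config("motif_change_prob must lie in [0, 1)")
  structure(list(background = background,
                 probs = stats::setNames(probs, c("A", "C", "G", "T")),
                 read_length = as.integer(read_length),
                 error_rate = error_rate,
                 motif_change_prob = motif_change_prob, seed = seed),
            class = "sim_config")
}

BASES <- c("A", "C", "G", "T")

# n x L integer base matrix (1..4) under the configured distribution.
base_matrix <- function(n, L, probs) {
  matrix(sample.int(4L, n * L, replace = TRUE, prob = probs),
         nrow = n, ncol = L)
}

collapse_rows <- function(m) {
  if (nrow(m) == 0L) return(character())
  do.call(paste0, as.data.frame(matrix(BASES[m], nrow = nrow(m))))
}

# Constant-rate substitution errors on an integer base matrix.
apply_errors <- function(m, error_rate) {
  if (error_rate <= 0 || length(m) == 0L) return(m)
  hit <- which(runif(length(m)) < error_rate)
  if (length(hit)) {
    # shift by 1..3 mod 4: always a different base
    m[hit] <- ((m[hit] - 1L + sample.int(3L, length(hit), replace = TRUE)) %% 4L) + 1L
  }
  m
}

#' Background reads
#'
#' Pseudorandom reads of i.i.d. nucleotides under the configured
#' background distribution. Sequencing error is not applied (substituting
#' an i.i.d. base leaves the distribution unchanged).
#'
#' @param config A [sim_config()].
#' @param n Number of reads.
#' @param seed Seed; defaults to `config$seed`. The same seed always
#'   yields the same reads.
#' @return Character vector of `n` reads of length `config$read_length`.
#' @export
background_reads <- function(config, n, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(seed, collapse_rows(base_matrix(n, config$read_length,
                                            config$probs)))
}

#' A read carrying a repeat tract
#'
#' Builds a background read and overwrites positions
#' `[offset, offset + repeat_nt)` with a periodic motif tract. Each full
#' motif copy is independently altered (one random substitution within the
#' copy) with probability `config$motif_change_prob`; afterwards every
#' base is substituted with probability `config$error_rate`. The read is
#' labelled repeat-informative when it carries at least 45 nt of
#' repetitive sequence.
#'
#' @param config A [sim_config()].
#' @param motif Motif string (1-15 nt over A/C/G/T).
#' @param repeat_nt Tract length in nt, `1 <= repeat_nt <= read_length`.
#' @param offset 0-based tract start; `NULL` places it uniformly at
#'   random.
#' @param seed Seed; defaults to `config$seed`.
#' @return List with `sequence` and `label` (`repeat_nt >= 45`).
#' @export
repeat_read <- function(config, motif, repeat_nt, offset = NULL,
                        seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  L <- config$read_length
  repeat_nt <- as.integer(repeat_nt)
  if (repeat_nt < 1L || repeat_nt > L)
    stop_config("repeat_nt must lie in 1..read_length")
  if (nchar(motif) < 1L || nchar(motif) > 15L || grepl("[^ACGT]", motif))
    stop_config("motif must be 1-15 nt over A/C/G/T")
  if (!is.null(offset) && (offset < 0L || offset > L - repeat_nt))
    stop_config("offset must lie in 0..(read_length - repeat_nt)")
  seqs <- with_seed(seed, {
    off <- if (is.null(offset)) sample.int(L - repeat_nt + 1L, 1L) - 1L
           else as.integer(offset)
    repeat_reads_vec(config, nchar(motif), repeat_nt, offsets = off,
                     motifs = motif)
  })
  list(sequence = seqs, label = repeat_nt >= 45L)
}

# Vectorised generator behind repeat_read / class simulation. Each read i
# gets tract repeat_nts[i] of motif motifs[i] at offsets[i] (0-based;
# sampled uniformly when NULL). Returns character vector.
repeat_reads_vec <- function(config, motif_lens, repeat_nts, offsets = NULL,
                             motifs = NULL) {
  L <- config$read_length
  n <- max(length(motif_lens), length(repeat_nts))
  motif_lens <- rep_len(motif_lens, n)
  repeat_nts <- rep_len(repeat_nts, n)
  if (is.null(motifs)) {
    motifs <- vapply(motif_lens, function(k) {
      paste(BASES[sample.int(4L, k, replace = TRUE)], collapse = "")
    }, character(1))
  } else {
    motifs <- rep_len(motifs, n)
  }
  if (is.null(offsets)) {
    offsets <- vapply(repeat_nts, function(rn) {
      sample.int(L - rn + 1L, 1L) - 1L
    }, integer(1))
  } else {
    offsets <- rep_len(as.integer(offsets), n)
  }

  n_copies <- ceiling(repeat_nts / motif_lens)
  tracts <- character(n)
  for (i in seq_len(n)) {
    mc <- config$motif_change_prob
    if (mc > 0) {
      copies <- rep(motifs[i], n_copies[i])
      altered <- which(runif(n_copies[i]) < mc)
      for (a in altered) {
        ch <- strsplit(copies[a], "", fixed = TRUE)[[1]]
        pos <- sample.int(length(ch), 1L)
        ch[pos] <- BASES[sample(setdiff(1:4, match(ch[pos], BASES)), 1L)]
        copies[a] <- paste(ch, collapse = "")
      }
      tracts[i] <- substr(paste(copies, collapse = ""), 1L, repeat_nts[i])
    } else {
      tracts[i] <- substr(strrep(motifs[i], n_copies[i]), 1L, repeat_nts[i])
    }
  }

  bg <- collapse_rows(base_matrix(n, L, config$probs))
  reads <- paste0(substr(bg, 1L, offsets),
                  tracts,
                  substr(bg, offsets + repeat_nts + 1L, L))
  apply_errors_str(reads, config$error_rate)
}

# Substitution errors on assembled read strings.
apply_errors_str <- function(reads, error_rate) {
  if (error_rate <= 0 || length(reads) == 0L) return(reads)
  L <- nchar(reads)
  n_err <- rbinom(length(reads), L, error_rate)
  for (i in which(n_err > 0L)) {
    ch <- strsplit(reads[i], "", fixed = TRUE)[[1]]
    pos <- sample.int(L[i], n_err[i])
    cur <- match(ch[pos], BASES)
    ch[pos] <- BASES[((cur - 1L + sample.int(3L, n_err[i], replace = TRUE)) %% 4L) + 1L]
    reads[i] <- paste(ch, collapse = "")
  }
  reads
}

#' Simulated repeat expansion locus
#'
#' Assembles flank5 + motif tract + flank3. Flanks are background sequence
#' rejection-sampled until the package's own run detector finds no
#' repetition with tract >= 15 nt, emulating repeat-masked genomic flanks
#' without any reference download.
#'
#' @param config A [sim_config()].
#' @param motif Repeat motif.
#' @param n_copies Number of motif copies inserted.
#' @param flank_length Length of each flank (default 2500 nt).
#' @param seed Seed; defaults to `config$seed`.
#' @param max_tries Rejection-sampling budget per flank.
#' @return A `simulated_locus` list: `flank5`, `flank3`, `motif`,
#'   `n_copies`, `insert_start` (0-based, equal to `flank_length`),
#'   `tract_length` and the assembled `sequence`.
#' @export
simulated_locus <- function(config, motif, n_copies, flank_length = 2500L,
                            seed = config$seed, max_tries = 100L) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(seed, {
    draw_flank <- function() {
      for (t in seq_len(max_tries)) {
        fl <- collapse_rows(base_matrix(1L, flank_length, config$probs))
        if (nrow(find_runs(fl, min_tract = 15L)) == 0L) return(fl)
      }
      stop_stat("could not draw a repeat-free flank in ", max_tries,
                " tries; the background distribution is too repetitive")
    }
    flank5 <- draw_flank()
    flank3 <- draw_flank()
    tract <- strrep(motif, n_copies)
    structure(list(flank5 = flank5, flank3 = flank3, motif = motif,
                   n_copies = n_copies, insert_start = nchar(flank5),
                   tract_length = nchar(tract),
                   sequence = paste0(flank5, tract, flank3)),
              class = "simulated_locus")
  })
}

#' Reads sampled from a simulated locus
#'
#' Draws `round(depth * locus_length / read_length)` reads with start
#' positions uniform over the locus, applies the configured error model,
#' and labels each read repeat-informative when it overlaps the repeat
#' tract by at least 45 nt.
#'
#' @param locus A `simulated_locus`.
#' @param depth Target fold-coverage (> 0).
#' @param config A [sim_config()].
#' @param seed Seed; defaults to `config$seed`.
#' @return List with `sequence` (character), `label` (logical) and
#'   `start` (0-based start positions).
#' @export
simulate_locus_reads <- function(locus, depth, config, seed = config$seed) {
  stopifnot(inherits(locus, "simulated_locus"), inherits(config, "sim_config"))
  L <- config$read_length
  locus_len <- nchar(locus$sequence)
  if (locus_len < L) stop_config("locus shorter than the read length")
  if (depth <= 0) stop_config("depth must be positive")
  n_reads <- round(depth * locus_len / L)
  with_seed(seed, {
    starts <- sample.int(locus_len - L + 1L, n_reads, replace = TRUE) - 1L
    seqs <- substr(rep(locus$sequence, n_reads), starts + 1L, starts + L)
    seqs <- apply_errors_str(seqs, config$error_rate)
    t0 <- locus$insert_start
    t1 <- locus$insert_start + locus$tract_length
    overlap <- pmax(0L, pmin(starts + L, t1) - pmax(starts, t0))
    list(sequence = seqs, label = overlap >= 45L, start = starts)
  })
}

#' Synthetic case-control cohort fixture
#'
#' Writes one FASTA file per sample plus a manifest TSV (sample_id, path,
#' label). Controls are pure background read sets. Cases draw
#' `round(depth * locus_length / read_length)` reads from a simulated
#' expansion locus carrying `case_repeat_nt` nt of `motif`, topped up with
#' background reads so every sample holds exactly `reads_per_sample`
#' reads. Byte-identical output under a fixed seed.
#'
#' @param n_cases,n_controls Sample counts (>= 1).
#' @param motif Expansion motif (default `"AGC"`).
#' @param case_repeat_nt Total repeat tract length at the simulated locus
#'   (nt).
#' @param reads_per_sample Library size per sample.
#' @param config A [sim_config()].
#' @param dir Output directory (created if needed).
#' @param depth Locus fold-coverage in cases (default 30).
#' @param flank_length Locus flank length (default 2500 nt).
#' @param seed Seed; defaults to `config$seed`.
#' @return Path to the manifest file, invisibly; the manifest labels cases
#'   `"case"` and controls `"control"`.
#' @export
simulate_cohort <- function(n_cases, n_controls, motif = "AGC",
                            case_repeat_nt = 150L, reads_per_sample = 10000L,
                            config = sim_config(), dir = tempfile("cohort"),
                            depth = 30, flank_length = 2500L,
                            seed = config$seed) {
  if (n_cases < 1L || n_controls < 1L)
    stop_config("need at least one case and one control")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- derive_seeds(seed, n_cases + n_controls + 1L)
  locus <- simulated_locus(config, motif,
                           n_copies = ceiling(case_repeat_nt / nchar(motif)),
                           flank_length = flank_length, seed = seeds[[1]])
  n_locus_reads <- round(depth * nchar(locus$sequence) / config$read_length)
  if (n_locus_reads >= reads_per_sample)
    stop_config("reads_per_sample too small for the requested locus depth")

  rows <- list()
  write_sample <- function(sample_id, seqs) {
    path <- file.path(dir, paste0(sample_id, ".fasta"))
    write_reads_fasta(stats::setNames(seqs, paste0(sample_id, "_r",
                                                   seq_along(seqs))), path)
    basename(path)
  }
  for (i in seq_len(n_cases)) {
    sid <- sprintf("case_%02d", i)
    s <- seeds[[1L + i]]
    seqs <- with_seed(s, {
      lr <- simulate_locus_reads(locus, depth, config, seed = NULL)
      bg <- background_reads(config, reads_per_sample - n_locus_reads,
                             seed = NULL)
      c(lr$sequence, bg)
    })
    rows[[length(rows) + 1L]] <- data.frame(sample_id = sid,
                                            path = write_sample(sid, seqs),
                                            label = "case")
  }
  for (i in seq_len(n_controls)) {
    sid <- sprintf("control_%02d", i)
    s <- seeds[[1L + n_cases + i]]
    seqs <- with_seed(s, background_reads(config, reads_per_sample,
                                          seed = NULL))
    rows[[length(rows) + 1L]] <- data.frame(sample_id = sid,
                                            path = write_sample(sid, seqs),
                                            label = "control")
  }
  manifest <- do.call(rbind, rows)
  manifest_path <- file.path(dir, "manifest.tsv")
  write.table(manifest, manifest_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(manifest_path)
}

# Simulated read classes for classifier calibration/evaluation.
# Positives carry 45..L nt of repeat; negatives are either pure
# background ("background") or reads carrying 0..44 nt of repeat
# ("labelled", the negatives of the 45-nt informative-read rule).
simulate_classifier_classes <- function(config, read_length, n_per_class,
                                        negatives = c("background", "labelled"),
                                        max_motif_nt = 6L, seed = NULL) {
  negatives <- match.arg(negatives)
  cfg <- config
  cfg$read_length <- as.integer(read_length)
  L <- cfg$read_length
  if (L < 45L) stop_config("read length below the 45-nt labelling rule")
  with_seed(seed, {
    pos <- repeat_reads_vec(cfg,
                            motif_lens = sample.int(max_motif_nt,
                                                    n_per_class,
                                                    replace = TRUE),
                            repeat_nts = sample(45:L, n_per_class,
                                                replace = TRUE))
    neg <- if (negatives == "background") {
      collapse_rows(base_matrix(n_per_class, L, cfg$probs))
    } else {
      rn <- sample(0:44, n_per_class, replace = TRUE)
      out <- character(n_per_class)
      zero <- rn == 0L
      out[zero] <- collapse_rows(base_matrix(sum(zero), L, cfg$probs))
      if (any(!zero)) {
        out[!zero] <- repeat_reads_vec(
          cfg,
          motif_lens = sample.int(max_motif_nt, sum(!zero), replace = TRUE),
          repeat_nts = rn[!zero]
        )
      }
      out
    }
    list(positive = pos, negative = neg)
  })
}

#' Evaluate the compression-ratio classifier on fresh simulated reads
#'
#' Simulates labelled reads (positives carry at least 45 nt of repeat
#' tract), classifies each with [is_candidate()] under the supplied
#' threshold table, and reports the confusion-matrix metrics against the
#' 45-nt labelling. The negative class follows the same two designs as
#' [calibrate_thresholds()].
#'
#' @param config A [sim_config()]; `config$read_length` selects the
#'   threshold entry.
#' @param table A `threshold_table` covering the read length.
#' @param n_per_class Reads per class (>= 1).
#' @param negatives `"labelled"` (default: negatives carry 0-44 nt of
#'   repeat) or `"background"` (pure pseudorandom reads).
#' @param max_motif_nt Longest simulated motif (default 6).
#' @param seed Optional seed.
#' @return List with `sensitivity`, `specificity`, `threshold`,
#'   `read_length`, `negatives` and the confusion counts `tp`, `fn`, `tn`,
#'   `fp`.
#' @export
evaluate_classifier <- function(config, table, n_per_class,
                                negatives = c("labelled", "background"),
                                max_motif_nt = 6L, seed = NULL) {
  negatives <- match.arg(negatives)
  if (n_per_class < 1L) stop_config("n_per_class must be >= 1")
  L <- config$read_length
  t_L <- threshold_for(table, L)
  cls <- simulate_classifier_classes(config, L, n_per_class, negatives,
                                     max_motif_nt, seed = seed)
  pos_call <- compression_ratio(cls$positive)$c_ratio <= t_L
  neg_call <- compression_ratio(cls$negative)$c_ratio <= t_L
  list(sensitivity = mean(pos_call), specificity = mean(!neg_call),
       threshold = t_L, read_length = L, negatives = negatives,
       tp = sum(pos_call), fn = sum(!pos_call),
       tn = sum(!neg_call), fp = sum(neg_call))
}
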