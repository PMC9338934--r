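#' Exact maximal repetitions (runs) in a read
#'
#' Finds every substring whose minimal period p satisfies tract length
#' >= 2p (at least two full copies) and which cannot be extended in either
#' direction while keeping that period - the standard "runs" of a string.
#' Detection is exact; fractional trailing copies extend the tract (e.g.
#' `"AGCAGCA"` is one run of tract 7, period 3), and positions holding `N`
#' belong to no run. Each run is reported once, with its minimal period.
#'
#' @param sequence A single nucleotide string.
#' @param min_tract Minimum tract length (nt) to report; default 9
#'   suppresses ubiquitous short dinucleotide noise without affecting
#'   downstream scoring windows.
#' @return A data frame sorted by (start, period) with columns `start`
#'   (0-based inclusive), `end` (0-based exclusive), `period`, `motif`
#'   (the leading `period` characters), `canonical_motif`, `tract_length`
#'   and `purity` (always 1 under exact detection; kept for file-format
#'   compatibility).
#' @examples
#' find_runs("ATATATCGCGCG", min_tract = 4)
#' @export
find_runs <- function(sequence, min_tract = 9L) {
  if (!is.character(sequence) || length(sequence) != 1L || is.na(sequence) ||
      nchar(sequence) == 0L)
    stop_config("sequence must be a single non-empty string")
  min_tract <- as.integer(min_tract)
  if (min_tract < 2L) stop_config("min_tract must be >= 2")
  raw <- find_runs_cpp(sequence, min_tract)
  motif <- substr(rep(sequence, length(raw$start)),
                  raw$start + 1L, raw$start + raw$period)
  data.frame(
    start = raw$start, end = raw$end, period = raw$period, motif = motif,
    canonical_motif = if (length(motif)) canonical_motif(motif) else character(),
    tract_length = raw$end - raw$start,
    purity = rep(1, length(raw$start))
  )
}

#' Canonical STR motif class
#'
#' Reduces a motif to its primitive root (so `"ATAT"` collapses to
#' `"AT"`), then returns the lexicographically smallest string (A < C < G
#' < T) among all cyclic rotations of the root and of its reverse
#' complement. Strand and phase are thereby factored out: CAG, CTG and GCA
#' all map to AGC, and GAA/TTC map to AAG - the reporting convention used
#' for repeat-expansion motifs.
#'
#' @param motif Character vector of motifs over `A/C/G/T`.
#' @return Character vector of canonical motif classes.
#' @examples
#' canonical_motif(c("CTG", "GAA", "ATAT"))
#' @export
canonical_motif <- function(motif) {
  if (length(motif) == 0L) return(character())
  if (any(is.na(motif)) || any(nchar(motif) == 0L))
    stop_config("motifs must be non-empty strings")
  if (any(grepl("[^ACGT]", motif)))
    stop_config("motif contains characters outside A/C/G/T ",
                "(runs never contain N by construction)")
  vapply(motif, canonical_motif_one, character(1), USE.NAMES = FALSE)
}

canonical_motif_one <- function(m) {
  root <- primitive_root(m)
  min(c(rotations(root), rotations(revcomp(root))))
}

primitive_root <- function(m) {
  k <- nchar(m)
  for (d in seq_len(k - 1L)) {
    if (k %% d == 0L && strrep(substr(m, 1L, d), k %/% d) == m)
      return(substr(m, 1L, d))
  }
  m
}

rotations <- function(m) {
  k <- nchar(m)
  doubled <- paste0(m, m)
  substring(doubled, seq_len(k), seq_len(k) + k - 1L)
}

#' Reverse complement of nucleotide strings
#'
#' @param x Character vector over `A/C/G/T/N`.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  comp <- chartr("ACGTN", "TGCAN", x)
  vapply(comp, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Enumerate canonical motif classes
#'
#' All distinct canonical motif classes whose canonical length lies in
#' `[k_min, k_max]`, obtained by canonicalising every k-mer in the range
#' and discarding classes whose primitive root falls outside it. The
#' counts per length are fixed combinatorial constants (2, 4, 10, 33, 102
#' and 350 for k = 1..6); tri- through pentamers total 145 classes.
#'
#' @param k_min,k_max Motif length bounds, `1 <= k_min <= k_max <= 6` in
#'   the default build.
#' @return Sorted character vector of canonical motifs.
#' @examples
#' length(enumerate_motif_classes(3, 5))  # 145
#' @export
enumerate_motif_classes <- function(k_min = 1L, k_max = 6L) {
  k_min <- as.integer(k_min); k_max <- as.integer(k_max)
  if (k_min < 1L || k_max < k_min)
    stop_config("require 1 <= k_min <= k_max")
  if (k_max > 6L)
    stop_config("k_max > 6 is not supported in the default build; ",
                "canonicalise longer motifs with canonical_motif() directly")
  bases <- c("A", "C", "G", "T")
  out <- unlist(lapply(k_min:k_max, function(k) {
    grid <- do.call(expand.grid,
                    c(rep(list(bases), k), stringsAsFactors = FALSE))
    kmers <- do.call(paste0, grid)
    unique(canonical_motif(kmers))
  }))
  out <- unique(out)
  sort(out[nchar(out) >= k_min & nchar(out) <= k_max])
}

#' Scan one read for repeats, applying the complexity filter first
#'
#' Computes the read's compression ratio, short-circuits to an empty
#' result when the read is not a candidate, and otherwise returns
#' [find_runs()] output (motifs already canonicalised).
#'
#' @param sequence A single read sequence.
#' @param table A `threshold_table` covering the read's length.
#' @param min_tract Minimum tract length, as in [find_runs()].
#' @return A run data frame (possibly empty).
#' @export
scan_read <- function(sequence, table, min_tract = 9L) {
  cr <- compression_ratio(sequence)
  if (!is_candidate(cr$c_ratio, cr$input_bytes, table))
    return(empty_runs())
  find_runs(sequence, min_tract = min_tract)
}

empty_runs <- function() {
  data.frame(start = integer(), end = integer(), period = integer(),
             motif = character(), canonical_motif = character(),
             tract_length = integer(), purity = numeric())
}

#' Scan a read set for repeats
#'
#' Vectorised per-sample processing: compression filter, then exact run
#' detection on candidate reads only.
#'
#' @param read_set A `read_set` from [stream_reads()].
#' @param table A `threshold_table` covering every observed read length.
#' @param min_tract Minimum tract length, as in [find_runs()].
#' @return A data frame of runs with a leading `read_id` column; the
#'   number of candidate reads is attached as attribute
#'   `n_candidates`.
#' @export
scan_reads <- function(read_set, table, min_tract = 9L) {
  stopifnot(inherits(read_set, "read_set"))
  empty <- data.frame(read_id = character(), start = integer(),
                      end = integer(), period = integer(),
                      motif = character(), canonical_motif = character(),
                      tract_length = integer(), purity = numeric())
  if (read_set$stats$n_reads == 0L)
    return(structure(empty, n_candidates = 0L))
  cr <- compression_ratio(read_set$sequence)
  cand <- is_candidate(cr$c_ratio, cr$input_bytes, table)
  idx <- which(cand)
  if (length(idx) == 0L) return(structure(empty, n_candidates = 0L))
  raw <- find_runs_batch_cpp(read_set$sequence[idx], as.integer(min_tract))
  if (length(raw$start) == 0L)
    return(structure(empty, n_candidates = length(idx)))
  seqs <- read_set$sequence[idx][raw$read]
  motif <- substr(seqs, raw$start + 1L, raw$start + raw$period)
  out <- data.frame(
    read_id = read_set$read_id[idx][raw$read],
    start = raw$start, end = raw$end, period = raw$period, motif = motif,
    canonical_motif = canonical_motif(motif),
    tract_length = raw$end - raw$start,
    purity = rep(1, length(raw$start))
  )
  structure(out, n_candidates = length(idx))
}
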