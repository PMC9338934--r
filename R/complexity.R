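#' Compression convention used for the complexity ratio
#'
#' The ratio C is defined over the bare DEFLATE stream: zlib at level 1
#' (its fastest setting), raw encoding (windowBits -15, so no zlib or gzip
#' header/trailer), memLevel 8. Header bytes would shift every ratio
#' additively, so only the stream itself is counted; one nucleotide
#' character equals one input byte.
#'
#' @return A single string identifying the convention, recorded in
#'   threshold tables and run manifests.
#' @export
deflate_convention <- function() {
  "raw-deflate/level=1/windowBits=-15/memLevel=8"
}

#' Per-read compression ratio C
#'
#' C is the size in bytes of the compressed read divided by the size in
#' bytes of the read itself. Repetitive sequence compresses well, so low C
#' flags candidate repeat-bearing reads.
#'
#' @param sequence Character vector of nucleotide strings (each length
#'   >= 1).
#' @return A data frame with one row per sequence: `input_bytes`,
#'   `output_bytes` and `c_ratio`. Deterministic for fixed input (see
#'   [deflate_convention()]).
#' @examples
#' compression_ratio(c(strrep("A", 150), strrep("ACG", 50)))
#' @export
compression_ratio <- function(sequence) {
  if (length(sequence) == 0L)
    return(data.frame(input_bytes = integer(), output_bytes = integer(),
                      c_ratio = numeric()))
  input_bytes <- nchar(sequence)
  if (anyNA(sequence) || any(input_bytes == 0L))
    stop_config("compression ratio is undefined for empty sequences")
  output_bytes <- deflate_sizes_cpp(sequence)
  data.frame(input_bytes = input_bytes, output_bytes = output_bytes,
             c_ratio = output_bytes / input_bytes)
}

#' Construct a threshold table
#'
#' A threshold table maps read length to the maximum compression ratio C
#' at which a read is still considered a repeat candidate. Lookup of an
#' absent read length fails loudly rather than interpolating.
#'
#' @param read_length Integer vector of read lengths (nt).
#' @param threshold Numeric vector of thresholds t_L (> 0).
#' @param sensitivity,specificity Optional calibration metrics per length.
#' @param background Background distribution name used in calibration.
#' @param seed Calibration seed.
#' @param provenance `"builtin"` or `"calibrated"`.
#' @return A `threshold_table` data frame.
#' @export
threshold_table <- function(read_length, threshold, sensitivity = NA_real_,
                            specificity = NA_real_, background = NA_character_,
                            seed = NA_integer_,
                            provenance = c("calibrated", "builtin")) {
  provenance <- match.arg(provenance)
  read_length <- as.integer(read_length)
  if (any(duplicated(read_length)))
    stop_config("duplicate read lengths in threshold table")
  if (any(!is.finite(threshold)) || any(threshold <= 0))
    stop_config("all thresholds must be positive")
  tab <- data.frame(read_length = read_length, threshold = threshold,
                    sensitivity = sensitivity, specificity = specificity,
                    background = background, seed = seed)
  tab <- tab[order(tab$read_length), , drop = FALSE]
  rownames(tab) <- NULL
  structure(tab, provenance = provenance,
            convention = deflate_convention(),
            class = c("threshold_table", "data.frame"))
}

#' Look up the threshold for a read length
#'
#' @param table A `threshold_table`.
#' @param read_length Integer read length.
#' @return The threshold t_L.
#' @export
threshold_for <- function(table, read_length) {
  stopifnot(inherits(table, "threshold_table"))
  hit <- match(as.integer(read_length), table$read_length)
  if (anyNA(hit))
    stop_config("no threshold for read length ",
                paste(read_length[is.na(hit)], collapse = ", "),
                " nt; run calibrate_thresholds() for this length")
  table$threshold[hit]
}

#' Is a read a repeat candidate?
#'
#' A read passes when its compression ratio is at or below the threshold
#' for its length (the boundary is inclusive: filter false positives are
#' cheap, they merely reach the repeat detector).
#'
#' @param c_ratio Numeric vector of compression ratios.
#' @param read_length Integer vector (length 1 or matching `c_ratio`).
#' @param table A `threshold_table` covering every supplied length.
#' @return Logical vector.
#' @export
is_candidate <- function(c_ratio, read_length, table) {
  c_ratio <= threshold_for(table, read_length)
}

#' Calibrate compression-ratio thresholds by simulation
#'
#' For each read length, simulates labelled repeat-informative reads
#' (tract length uniform on 45..L nt) and an equally sized negative class,
#' computes C for all reads, and picks the threshold maximising Youden's
#' J = sensitivity + specificity - 1 over the observed C values (ties
#' resolve to the largest threshold, favouring sensitivity). Two negative
#' designs are available, mirroring the two simulation designs the method
#' is usually validated on:
#' \describe{
#'   \item{`"background"`}{pure pseudorandom reads - repeat-containing
#'     reads versus background sequence.}
#'   \item{`"labelled"`}{reads carrying 0-44 nt of repeat tract, i.e. the
#'     negatives of the 45-nt informative-read labelling; these include
#'     near-boundary tracts and give more conservative thresholds.}
#' }
#'
#' @param read_lengths Integer vector of read lengths to calibrate.
#' @param config A [sim_config()]; its error rate, impurity and background
#'   distribution define the simulated reads.
#' @param n_reads_per_class Reads per class per length (>= 1000 for stable
#'   estimates).
#' @param seed Integer seed; identical seeds give identical tables.
#' @param negatives Negative-class design, see above.
#' @param max_motif_nt Longest motif simulated in the positive class.
#' @return A `threshold_table` with achieved in-sample sensitivity and
#'   specificity per read length.
#' @export
calibrate_thresholds <- function(read_lengths, config = sim_config(),
                                 n_reads_per_class = 2000, seed = NULL,
                                 negatives = c("background", "labelled"),
                                 max_motif_nt = 6L) {
  negatives <- match.arg(negatives)
  if (n_reads_per_class < 1000)
    stop_config("n_reads_per_class must be >= 1000 for stable calibration")
  seeds <- derive_seeds(seed, length(read_lengths))
  rows <- lapply(seq_along(read_lengths), function(k) {
    L <- as.integer(read_lengths[k])
    cls <- simulate_classifier_classes(config, L, n_reads_per_class,
                                       negatives, max_motif_nt,
                                       seed = seeds[[k]])
    pos_c <- compression_ratio(cls$positive)$c_ratio
    neg_c <- compression_ratio(cls$negative)$c_ratio
    th <- youden_threshold(pos_c, neg_c)
    data.frame(read_length = L, threshold = th$threshold,
               sensitivity = th$sensitivity, specificity = th$specificity)
  })
  rows <- do.call(rbind, rows)
  threshold_table(rows$read_length, rows$threshold,
                  sensitivity = rows$sensitivity,
                  specificity = rows$specificity,
                  background = paste0(config$background, "/", negatives),
                  seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
                  provenance = "calibrated")
}

# Maximum-J threshold over the observed ratios; candidates are the
# observed values themselves (the decision rule is inclusive, c <= t).
youden_threshold <- function(pos_c, neg_c) {
  cand <- sort(unique(c(pos_c, neg_c)))
  spos <- sort(pos_c)
  sneg <- sort(neg_c)
  sens <- findInterval(cand, spos) / length(spos)
  spec <- 1 - findInterval(cand, sneg) / length(sneg)
  j <- sens + spec - 1
  if (max(j) <= 0)
    stop_stat("classes are inseparable: Youden's J <= 0 at every threshold; ",
              "check the simulation configuration")
  best <- which(j == max(j))
  pick <- best[length(best)]  # largest threshold among ties
  list(threshold = cand[pick], sensitivity = sens[pick],
       specificity = spec[pick], j = j[pick])
}

#' Read or write a threshold table as TSV
#'
#' Columns: read_length, threshold, sensitivity, specificity, background,
#' seed. Comment lines record provenance and the compression convention.
#'
#' @param table A `threshold_table`.
#' @param path File path.
#' @return `write_threshold_table()` returns `path` invisibly;
#'   `read_threshold_table()` returns a `threshold_table`.
#' @export
write_threshold_table <- function(table, path) {
  stopifnot(inherits(table, "threshold_table"))
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(c(paste0("#provenance\t", attr(table, "provenance")),
               paste0("#convention\t", attr(table, "convention"))), con)
  write.table(as.data.frame(table), con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_threshold_table
#' @export
read_threshold_table <- function(path) {
  lines <- readLines(path)
  meta <- lines[startsWith(lines, "#")]
  prov <- sub("^#provenance\t", "", meta[startsWith(meta, "#provenance")])
  tab <- read.delim(text = lines[!startsWith(lines, "#")], sep = "\t",
                    stringsAsFactors = FALSE)
  threshold_table(tab$read_length, tab$threshold, tab$sensitivity,
                  tab$specificity, tab$background, tab$seed,
                  provenance = if (length(prov) && prov == "builtin")
                    "builtin" else "calibrated")
}

#' Built-in threshold table
#'
#' Thresholds shipped with the package, calibrated by
#' [calibrate_thresholds()] under the uniform background at zero error for
#' read lengths 75, 100, 124, 125 and 150 nt (20000 reads per class,
#' seed 101, background negatives). Recalibrate for other lengths, other
#' backgrounds or error models.
#'
#' @return A `threshold_table` with provenance `"builtin"`.
#' @export
default_thresholds <- function() {
  path <- system.file("extdata", "thresholds_uniform.tsv",
                      package = "strsift", mustWork = TRUE)
  tab <- read_threshold_table(path)
  attr(tab, "provenance") <- "builtin"
  tab
}
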