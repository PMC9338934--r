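#' Read and normalise sequencing reads
#'
#' Loads reads from FASTQ, FASTA (both optionally gzip-compressed; gzip is
#' detected from the magic bytes, not the file name) or headered SAM text
#' (sequence column only). Sequences are uppercased and any character
#' outside `A/C/G/T/N` is mapped to `N`. Reads longer than `trim_to` are
#' truncated to their first `trim_to` nucleotides; shorter reads are kept
#' untrimmed, so trimming downsamples long reads rather than filtering
#' short ones. Qualities and pairing information are ignored; paired-end
#' files are simply two read streams whose counts both contribute to the
#' library size.
#'
#' @param path Path to the read file.
#' @param format One of `"auto"`, `"fastq"`, `"fasta"`, `"sam"`. `"auto"`
#'   distinguishes FASTQ from FASTA by the first record character; SAM
#'   must be requested explicitly.
#' @param trim_to Optional integer: truncate reads longer than this many
#'   nucleotides.
#' @return An object of class `read_set`: a list with `read_id`
#'   (character), `sequence` (character) and `stats`, a `library_stats`
#'   list holding `n_reads`, `read_length_mode` and the post-trim
#'   `read_length_histogram`. An empty file yields `n_reads = 0`.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">r1", "ACGTACGTAC", ">r2", "AAAAAAAAAA"), fa)
#' rs <- stream_reads(fa)
#' rs$stats$n_reads
#' @export
stream_reads <- function(path, format = c("auto", "fastq", "fasta", "sam"),
                         trim_to = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_parse("read file not found: ", path)
  if (!is.null(trim_to)) {
    trim_to <- as.integer(trim_to)
    if (is.na(trim_to) || trim_to < 1L)
      stop_config("trim_to must be a positive integer")
  }

  if (format == "auto") format <- sniff_format(path)

  if (format == "sam") {
    reads <- read_sam_sequences(path)
  } else {
    if (format == "fastq") validate_fastq(path)
    set <- tryCatch(
      Biostrings::readDNAStringSet(path, format = format),
      error = function(e) {
        stop_parse("failed to parse ", path, " as ", format, ": ",
                   conditionMessage(e))
      }
    )
    reads <- as.character(set)
    names(reads) <- sub("\\s.*$", "", names(set) %||% character())
  }

  reads <- normalise_sequences(reads)
  if (!is.null(trim_to)) {
    long <- nchar(reads) > trim_to
    reads[long] <- substr(reads[long], 1L, trim_to)
  }

  structure(
    list(read_id = names(reads) %||% character(),
         sequence = unname(reads),
         stats = library_stats(nchar(reads))),
    class = "read_set"
  )
}

# First printable record character decides FASTQ vs FASTA.
sniff_format <- function(path) {
  con <- open_maybe_gz(path)
  on.exit(close(con))
  repeat {
    ln <- readLines(con, n = 1L, warn = FALSE)
    if (length(ln) == 0L) return("fasta")  # empty: either parser yields 0 reads
    if (nzchar(trimws(ln))) break
  }
  first <- substr(trimws(ln), 1L, 1L)
  if (first == "@") "fastq" else if (first == ">") "fasta"
  else stop_parse("cannot auto-detect format of ", path,
                  ": first record starts with '", first, "'")
}

is_gzipped <- function(path) {
  magic <- readBin(path, "raw", n = 2L)
  length(magic) == 2L && magic[1] == as.raw(0x1f) && magic[2] == as.raw(0x8b)
}

open_maybe_gz <- function(path) {
  if (is_gzipped(path)) gzfile(path, "rt") else file(path, "rt")
}

# Sequence-only SAM text streaming: column 10, '*' placeholders skipped.
read_sam_sequences <- function(path) {
  con <- open_maybe_gz(path)
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  lines <- lines[!startsWith(lines, "@") & nzchar(lines)]
  if (length(lines) == 0L) return(stats::setNames(character(), character()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 10L)
  if (length(bad))
    stop_parse("SAM record ", bad[1], " in ", path, " has fewer than 10 fields")
  seqs <- vapply(fields, `[[`, character(1), 10L)
  ids <- vapply(fields, `[[`, character(1), 1L)
  keep <- seqs != "*"
  stats::setNames(seqs[keep], ids[keep])
}

normalise_sequences <- function(x) {
  if (length(x) == 0L) return(x)
  x <- toupper(x)
  needs <- grepl("[^ACGTN]", x)
  x[needs] <- gsub("[^ACGTN]", "N", x[needs])
  x
}

# Structural FASTQ validation (4-line records, matching sequence/quality
# lengths); the DNAStringSet parser does not check qualities, so mismatches
# are caught here, naming the first offending record.
validate_fastq <- function(path) {
  con <- open_maybe_gz(path)
  on.exit(close(con))
  rec <- 0L
  repeat {
    chunk <- readLines(con, n = 40000L, warn = FALSE)
    if (length(chunk) == 0L) break
    if (length(chunk) %% 4L != 0L)  # chunk size is a multiple of 4, so a
      stop_parse("malformed FASTQ file ", path, ": line count is not a ",
                 "multiple of 4")   # partial chunk only occurs at EOF
    n <- length(chunk) %/% 4L
    seqs <- chunk[seq_len(n) * 4L - 2L]
    quals <- chunk[seq_len(n) * 4L]
    bad <- which(nchar(seqs) != nchar(quals))
    if (length(bad))
      stop_parse("malformed FASTQ record ", rec + bad[1], " in ", path,
                 ": sequence (", nchar(seqs[bad[1]]), " nt) and quality (",
                 nchar(quals[bad[1]]), " nt) lengths differ")
    rec <- rec + n
  }
  invisible(TRUE)
}

#' Library statistics for a set of read lengths
#'
#' @param lengths Integer vector of (post-trim) read lengths.
#' @return A `library_stats` list: `n_reads` (the library size n),
#'   `read_length_mode` (the modal read length j; ties resolve to the
#'   smallest length) and `read_length_histogram`.
#' @export
library_stats <- function(lengths) {
  lengths <- as.integer(lengths)
  if (length(lengths) == 0L) {
    return(structure(list(n_reads = 0L, read_length_mode = NA_integer_,
                          read_length_histogram = integer()),
                     class = "library_stats"))
  }
  hist <- table(lengths)
  lens <- as.integer(names(hist))
  counts <- as.integer(hist)
  mode <- lens[counts == max(counts)][1L]  # smallest length among ties
  structure(
    list(n_reads = length(lengths), read_length_mode = mode,
         read_length_histogram = stats::setNames(counts, lens)),
    class = "library_stats"
  )
}

#' Common read length for a mixed-length cohort
#'
#' Returns the minimum of the per-sample modal read lengths; re-processing
#' every sample with `trim_to` set to this value makes information-score
#' windows comparable across samples. Trimming downsamples the experiments
#' with longer reads and is recommended only where lengths are similar
#' (e.g. 150 vs 151 nt, or mixed 132/124 nt runs trimmed to 124 nt).
#'
#' @param stats_list List of `library_stats` objects, all with
#'   `n_reads > 0`.
#' @return Integer: the trim length.
#' @export
choose_common_length <- function(stats_list) {
  if (length(stats_list) == 0L) stop_config("no library statistics supplied")
  modes <- vapply(stats_list, function(s) {
    if (s$n_reads <= 0L) stop_config("choose_common_length requires n_reads > 0 for every sample")
    as.integer(s$read_length_mode)
  }, integer(1))
  min(modes)
}

#' Write reads to FASTA
#'
#' @param read_set A `read_set` (or named character vector of sequences).
#' @param path Output path; a `.gz` suffix writes gzip-compressed output.
#' @return `path`, invisibly.
#' @export
write_reads_fasta <- function(read_set, path) {
  seqs <- if (inherits(read_set, "read_set")) {
    stats::setNames(read_set$sequence, read_set$read_id)
  } else {
    read_set
  }
  set <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(set, filepath = path,
                              compress = grepl("\\.gz$", path))
  invisible(path)
}
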