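#' Summarise detected runs into a sample profile
#'
#' Aggregates per-read runs into a per-motif repeat count vector v, where
#' v_l is the number of runs of a canonical motif with tract length
#' exactly l nt. Every run counts (several runs of one motif within one
#' read each increment their cell); runs whose canonical motif is longer
#' than `max_motif_len` are dropped at this summarisation step even though
#' detection ran without a motif-length cap. Counts are stored raw, with
#' the library size n alongside, so the information score divides by n
#' exactly once.
#'
#' @param runs Run data frame from [scan_reads()] (columns
#'   `canonical_motif` and `tract_length`).
#' @param stats `library_stats` for the whole sample (all reads, not just
#'   candidates).
#' @param sample_id Sample identifier.
#' @param max_motif_len Longest canonical motif to keep (default 6, the
#'   conventional STR motif range).
#' @return A `sample_profile`: list with `sample_id`, `library_size` (n),
#'   `read_length` (the modal length j) and `counts`, a data frame
#'   (motif, tract_length, count).
#' @export
build_profile <- function(runs, stats, sample_id, max_motif_len = 6L) {
  stopifnot(inherits(stats, "library_stats"))
  if (stats$n_reads <= 0L)
    stop_config("cannot build a profile for an empty library")
  j <- stats$read_length_mode
  max_len <- max(as.integer(names(stats$read_length_histogram)))
  keep <- nchar(runs$canonical_motif) <= max_motif_len
  runs <- runs[keep, , drop = FALSE]
  if (nrow(runs) && any(runs$tract_length > max_len))
    stop_stat("internal consistency error: run tract length exceeds ",
              "the longest read in the library")
  counts <- if (nrow(runs)) {
    agg <- stats::aggregate(list(count = rep(1L, nrow(runs))),
                            by = list(motif = runs$canonical_motif,
                                      tract_length = runs$tract_length),
                            FUN = sum)
    agg[order(agg$motif, agg$tract_length), , drop = FALSE]
  } else {
    data.frame(motif = character(), tract_length = integer(),
               count = integer())
  }
  rownames(counts) <- NULL
  structure(list(sample_id = sample_id, library_size = stats$n_reads,
                 read_length = j, counts = counts),
            class = "sample_profile")
}

#' Per-motif information scores
#'
#' Computes s_m = (sum over i <= l <= j of v_l * l) / n for each motif m,
#' where v is the raw tract-length count vector, n the library size, j
#' defaults to the read length and i to floor(0.75 * j). The window keeps
#' only tracts spanning at least three quarters of the read - reads
#' dominated by repeat sequence - so the score measures how much long
#' repetitive sequence of each motif the sample contains, per read
#' sequenced. Counts are divided by n exactly once, which makes s_m
#' invariant under duplication of the whole library.
#'
#' @param profile A `sample_profile`.
#' @param i,j Optional window bounds on tract length (nt),
#'   `1 <= i <= j <= read_length`.
#' @return A `score_vector`: list with `sample_id`, `scores` (named
#'   numeric, one entry per motif present in the profile) and `window`
#'   `c(i, j)`.
#' @export
information_scores <- function(profile, i = NULL, j = NULL) {
  stopifnot(inherits(profile, "sample_profile"))
  j <- as.integer(j %||% profile$read_length)
  i <- as.integer(i %||% floor(0.75 * j))
  if (i > j) stop_config("window start i exceeds window end j")
  if (i < 1L || j > profile$read_length)
    stop_config("window [", i, ", ", j, "] outside 1..read_length (",
                profile$read_length, ")")
  cnt <- profile$counts
  in_window <- cnt$tract_length >= i & cnt$tract_length <= j
  contrib <- cnt$count[in_window] * cnt$tract_length[in_window]
  scores <- tapply(contrib, cnt$motif[in_window], sum) / profile$library_size
  all_motifs <- unique(cnt$motif)
  out <- stats::setNames(numeric(length(all_motifs)), all_motifs)
  out[names(scores)] <- as.numeric(scores)
  structure(list(sample_id = profile$sample_id, scores = out,
                 window = c(i = i, j = j)),
            class = "score_vector")
}

#' Assemble per-sample scores into a cohort matrix
#'
#' @param scores List of `score_vector` objects with unique sample IDs and
#'   identical windows (mixed windows indicate mixed read lengths; re-trim
#'   with [choose_common_length()] and reprocess).
#' @param labels Named character vector mapping sample_id to a group label
#'   (e.g. `"case"`, `"control"`, `"background"`).
#' @return A `cohort_matrix`: list with `scores` (dense samples x motifs
#'   matrix, absent motifs filled with 0), `labels` and `window`.
#' @export
assemble_cohort <- function(scores, labels) {
  if (length(scores) == 0L) stop_config("no score vectors supplied")
  ids <- vapply(scores, function(s) s$sample_id, character(1))
  if (any(duplicated(ids)))
    stop_config("duplicate sample_id: ",
                paste(unique(ids[duplicated(ids)]), collapse = ", "))
  windows <- vapply(scores, function(s) paste(s$window, collapse = ":"),
                    character(1))
  if (length(unique(windows)) != 1L)
    stop_config("score windows differ across samples; trim all samples to ",
                "a common read length (choose_common_length) and reprocess")
  missing_lab <- setdiff(ids, names(labels))
  if (length(missing_lab))
    stop_config("no label for sample(s): ", paste(missing_lab, collapse = ", "))
  motifs <- sort(unique(unlist(lapply(scores, function(s) names(s$scores)))))
  mat <- matrix(0, nrow = length(ids), ncol = length(motifs),
                dimnames = list(ids, motifs))
  for (s in scores) mat[s$sample_id, names(s$scores)] <- s$scores
  structure(list(scores = mat, labels = labels[ids],
                 window = scores[[1]]$window),
            class = "cohort_matrix")
}

#' Process one sample end to end
#'
#' Streams reads, applies the compression filter, detects runs and builds
#' the sample profile - the per-sample half of the workflow.
#'
#' @inheritParams stream_reads
#' @param table A `threshold_table`; defaults to [default_thresholds()].
#' @param sample_id Sample identifier; defaults to the file name.
#' @param min_tract,max_motif_len See [find_runs()] and [build_profile()].
#' @return A `sample_profile` with the candidate count attached as
#'   attribute `n_candidates`.
#' @export
process_sample <- function(path, table = default_thresholds(),
                           sample_id = NULL,
                           format = c("auto", "fastq", "fasta", "sam"),
                           trim_to = NULL, min_tract = 9L,
                           max_motif_len = 6L) {
  sample_id <- sample_id %||% sub("\\.(fa|fasta|fq|fastq|sam)(\\.gz)?$", "",
                                  basename(path))
  rs <- stream_reads(path, format = format, trim_to = trim_to)
  runs <- scan_reads(rs, table, min_tract = min_tract)
  prof <- build_profile(runs, rs$stats, sample_id,
                        max_motif_len = max_motif_len)
  attr(prof, "n_candidates") <- attr(runs, "n_candidates")
  prof
}

#' Read or write a sample profile as TSV
#'
#' Header lines `#sample_id`, `#library_size` and `#read_length` precede
#' columns motif, tract_length, count.
#'
#' @param profile A `sample_profile`.
#' @param path File path.
#' @return `write_profile()` returns `path` invisibly; `read_profile()`
#'   returns a `sample_profile`.
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "sample_profile"))
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(c(paste0("#sample_id\t", profile$sample_id),
               paste0("#library_size\t", profile$library_size),
               paste0("#read_length\t", profile$read_length)), con)
  write.table(profile$counts, con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  lines <- readLines(path)
  meta <- lines[startsWith(lines, "#")]
  get_meta <- function(key) {
    hit <- meta[startsWith(meta, paste0("#", key, "\t"))]
    if (length(hit) != 1L)
      stop_parse("profile ", path, " lacks header line #", key)
    sub(paste0("^#", key, "\t"), "", hit)
  }
  body <- lines[!startsWith(lines, "#")]
  counts <- if (length(body) > 1L) {
    read.delim(text = body, sep = "\t", stringsAsFactors = FALSE)
  } else {
    data.frame(motif = character(), tract_length = integer(),
               count = integer())
  }
  structure(list(sample_id = get_meta("sample_id"),
                 library_size = as.integer(get_meta("library_size")),
                 read_length = as.integer(get_meta("read_length")),
                 counts = counts),
            class = "sample_profile")
}

#' Read a cohort manifest
#'
#' A manifest is a TSV with columns `sample_id`, `path` and `label`;
#' `path` points at read files (for processing) or profile files (for
#' cohort analysis), resolved relative to the manifest's directory when
#' not absolute.
#'
#' @param path Manifest path.
#' @return A data frame with absolute paths.
#' @export
read_manifest <- function(path) {
  man <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    comment.char = "#")
  need <- c("sample_id", "path", "label")
  if (!all(need %in% names(man)))
    stop_parse("manifest ", path, " must have columns: ",
               paste(need, collapse = ", "))
  rel <- !grepl("^(/|[A-Za-z]:)", man$path)
  man$path[rel] <- file.path(dirname(normalizePath(path)), man$path[rel])
  man
}
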