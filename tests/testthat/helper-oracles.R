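# Independent oracles used across the suite. These deliberately share no
# code with the package internals they check.

# ---- maximal repetitions ---------------------------------------------------
# Exhaustive enumeration over all (start, end, period) triples using
# cumulative match tables: a substring [i, j] (1-based inclusive) is a run
# iff its minimal period p satisfies len >= 2p and the interval cannot be
# extended one position left or right while keeping period p. Positions
# holding N never match anything.
oracle_runs <- function(s, min_tract = 2L) {
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  n <- length(ch)
  empty <- data.frame(start = integer(), end = integer(), period = integer())
  if (n < 2L) return(empty)
  maxp <- n - 1L

  # cs[[p]][k+1] = number of matching positions among the first k
  cs <- vector("list", maxp)
  for (p in seq_len(maxp)) {
    ok <- ch[seq_len(n - p)] == ch[seq_len(n - p) + p] &
      ch[seq_len(n - p)] != "N"
    cs[[p]] <- c(0L, cumsum(ok))
  }
  periodic <- function(i, j, p) {
    # does [i, j] have period p? (needs at least one comparison)
    j - p >= i && cs[[p]][j - p + 1L] - cs[[p]][i] == j - p - i + 1L
  }

  out <- list()
  for (i in seq_len(n)) {
    for (j in i:n) {
      len <- j - i + 1L
      if (len < max(2L, min_tract)) next
      pmin <- 0L
      for (p in seq_len(len - 1L)) {
        if (periodic(i, j, p)) { pmin <- p; break }
      }
      if (pmin == 0L || len < 2L * pmin) next
      if (i > 1L && periodic(i - 1L, j, pmin)) next
      if (j < n && periodic(i, j + 1L, pmin)) next
      out[[length(out) + 1L]] <- c(i - 1L, j, pmin)  # 0-based half-open
    }
  }
  if (length(out) == 0L) return(empty)
  m <- do.call(rbind, out)
  df <- data.frame(start = m[, 1], end = m[, 2], period = m[, 3])
  df <- df[order(df$start, df$period), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# ---- canonical motif classes ----------------------------------------------
# Orbit construction: walk all k-mers, skip non-primitive ones, and count
# one class per orbit under rotation and reverse complement.
oracle_rotations <- function(s) {
  k <- nchar(s)
  vapply(seq_len(k) - 1L, function(r) {
    paste0(substr(s, r + 1L, k), substr(s, 1L, r))
  }, character(1))
}

oracle_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "", fixed = TRUE)[[1]]),
        collapse = "")
}

oracle_primitive <- function(s) {
  k <- nchar(s)
  for (d in seq_len(k - 1L)) {
    if (k %% d == 0L && strrep(substr(s, 1L, d), k %/% d) == s) return(FALSE)
  }
  TRUE
}

oracle_motif_classes <- function(k) {
  bases <- c("A", "C", "G", "T")
  grid <- do.call(expand.grid, c(rep(list(bases), k),
                                 stringsAsFactors = FALSE))
  kmers <- do.call(paste0, grid)
  seen <- new.env(hash = TRUE)
  reps <- character()
  for (s in kmers) {
    if (!is.null(seen[[s]])) next
    if (!oracle_primitive(s)) next
    orbit <- unique(c(oracle_rotations(s),
                      oracle_rotations(oracle_revcomp(s))))
    for (o in orbit) seen[[o]] <- TRUE
    reps <- c(reps, min(orbit))
  }
  sort(reps)
}

# ---- Benjamini-Hochberg step-up -------------------------------------------
# Literal definition: adj_(i) = min_{k >= i} (m * p_(k) / k), capped at 1,
# mapped back to input order.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj_sorted <- vapply(seq_len(m), function(i) {
    min(1, min(m * ps[i:m] / (i:m)))
  }, numeric(1))
  out <- numeric(m)
  out[o] <- adj_sorted
  out
}

# ---- exhaustive one-sided Mann-Whitney ------------------------------------
# Enumerates every labelling; U comes from wilcox.test so the statistic is
# computed independently of the package.
oracle_mw_exact <- function(case, control) {
  pooled <- c(case, control)
  n1 <- length(case)
  u_obs <- unname(suppressWarnings(
    wilcox.test(case, control, alternative = "greater", exact = FALSE)$statistic))
  idx <- utils::combn(length(pooled), n1)
  u_all <- apply(idx, 2, function(k) {
    unname(suppressWarnings(
      wilcox.test(pooled[k], pooled[-k], alternative = "greater",
                  exact = FALSE)$statistic))
  })
  list(u = u_obs, p = mean(u_all >= u_obs - 1e-9))
}

# ---- misc ------------------------------------------------------------------
random_dna <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1))
}

runs_key <- function(df) {
  paste(df$start, df$end, df$period, sep = ":")
}
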