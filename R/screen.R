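#' One-sided Mann-Whitney U test with a permutation null
#'
#' Tests whether case scores are stochastically larger than control
#' scores. U counts case-over-control wins with ties contributing 1/2
#' (computed from midranks). When the number of distinct label
#' arrangements C(n1+n2, n1) is at most `n_perm`, the null is enumerated
#' exhaustively and the exact one-sided p-value is returned; otherwise
#' `n_perm` random label permutations are drawn and the add-one estimator
#' p = (1 + #\{U* >= U\}) / (1 + n_perm) is used, which can never return 0.
#'
#' @param case_scores,control_scores Numeric vectors, both non-empty.
#' @param n_perm Number of permutations (>= 1000; default 10000).
#' @param seed Optional integer seed for the permutation draw.
#' @return List with `u` (the U statistic), `p_raw`, `method`
#'   (`"exact"` or `"permutation"`) and `n_used` (arrangements evaluated).
#' @examples
#' mw_permutation_test(c(3, 4, 5), c(0, 1, 2))  # U = 9, exact p = 0.05
#' @export
mw_permutation_test <- function(case_scores, control_scores,
                                n_perm = 10000L, seed = NULL) {
  n1 <- length(case_scores); n2 <- length(control_scores)
  if (n1 == 0L || n2 == 0L)
    stop_config("both groups must be non-empty")
  if (n_perm < 1000L) stop_config("n_perm must be >= 1000")
  pooled <- c(case_scores, control_scores)
  r <- rank(pooled)  # midranks
  u_of <- function(case_idx) sum(r[case_idx]) - n1 * (n1 + 1) / 2
  u <- u_of(seq_len(n1))
  n <- n1 + n2
  n_arrange <- choose(n, n1)
  if (n_arrange <= n_perm) {
    idx <- combn(n, n1)
    u_star <- colSums(matrix(r[idx], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- mean(u_star >= u - 1e-9)
    list(u = u, p_raw = p, method = "exact", n_used = ncol(idx))
  } else {
    u_star <- with_seed(seed, {
      vapply(seq_len(n_perm),
             function(b) u_of(sample.int(n, n1)), numeric(1))
    })
    p <- (1 + sum(u_star >= u - 1e-9)) / (1 + n_perm)
    list(u = u, p_raw = p, method = "permutation", n_used = n_perm)
  }
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment; a thin, input-validating
#' wrapper around [stats::p.adjust()].
#'
#' @param p_values Numeric vector of raw p-values in (0, 1].
#' @return Adjusted p-values, order-aligned with the input and capped
#'   at 1.
#' @export
bh_adjust <- function(p_values) {
  if (length(p_values) == 0L) return(numeric())
  if (any(!is.finite(p_values)) || any(p_values <= 0) || any(p_values > 1))
    stop_config("p-values must lie in (0, 1]")
  p.adjust(p_values, method = "BH")
}

#' Case-control motif screening across a cohort
#'
#' For every motif with a nonzero information score in at least one
#' sample, tests whether samples carrying `label_of_interest` have larger
#' scores than all remaining samples (one-sided Mann-Whitney with a
#' permutation null), then applies Benjamini-Hochberg correction across
#' exactly that motif set.
#'
#' @param cohort A `cohort_matrix` from [assemble_cohort()].
#' @param label_of_interest Label defining the case group; every other
#'   sample is a control.
#' @param n_perm Permutations per motif (default 10000).
#' @param alpha Significance threshold on the adjusted p-value
#'   (default 0.05).
#' @param seed Optional integer seed; per-motif permutation seeds are
#'   derived from it.
#' @return A data frame sorted by (p_adjusted, motif): `motif`,
#'   `u_statistic`, `p_raw`, `p_adjusted`, `n_case`, `n_control`,
#'   `significant`. Empty when no motif has a nonzero score.
#' @export
screen_cohort <- function(cohort, label_of_interest = "case",
                          n_perm = 10000L, alpha = 0.05, seed = NULL) {
  stopifnot(inherits(cohort, "cohort_matrix"))
  is_case <- cohort$labels == label_of_interest
  if (!any(is_case))
    stop_config("label '", label_of_interest, "' not present in the cohort")
  if (all(is_case))
    stop_config("no control samples: every sample carries label '",
                label_of_interest, "'")
  mat <- cohort$scores
  motifs <- colnames(mat)[colSums(mat != 0) > 0]
  if (length(motifs) == 0L) {
    return(data.frame(motif = character(), u_statistic = numeric(),
                      p_raw = numeric(), p_adjusted = numeric(),
                      n_case = integer(), n_control = integer(),
                      significant = logical()))
  }
  seeds <- derive_seeds(seed, length(motifs))
  res <- lapply(seq_along(motifs), function(k) {
    m <- motifs[k]
    t <- mw_permutation_test(mat[is_case, m], mat[!is_case, m],
                             n_perm = n_perm, seed = seeds[[k]])
    data.frame(motif = m, u_statistic = t$u, p_raw = t$p_raw)
  })
  out <- do.call(rbind, res)
  out$p_adjusted <- bh_adjust(out$p_raw)
  out$n_case <- sum(is_case)
  out$n_control <- sum(!is_case)
  out$significant <- out$p_adjusted < alpha
  out <- out[order(out$p_adjusted, out$motif), , drop = FALSE]
  rownames(out) <- NULL
  out
}
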