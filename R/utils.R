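# Internal helpers: classed conditions and seeded evaluation.

stop_parse <- function(...) {
  stop(errorCondition(paste0(...), class = c("strsift_parse_error", "error")))
}

stop_config <- function(...) {
  stop(errorCondition(paste0(...), class = c("strsift_config_error", "error")))
}

stop_stat <- function(...) {
  stop(errorCondition(paste0(...), class = c("strsift_stat_error", "error")))
}

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state. A NULL seed evaluates in the current state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop_config("seed must be a single finite number")
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a stream of child seeds from one user seed, kept within the
# 32-bit integer range R requires.
derive_seeds <- function(seed, n) {
  if (is.null(seed)) return(vector("list", n))
  as.list((as.double(seed) * 48271 + 7919 * seq_len(n)) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
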