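#' @keywords internal
"_PACKAGE"

# Deterministic seed fan-out: one user-facing seed is expanded into
# independent per-stage seeds so that e.g. data generation, weight init,
# batching, K-means and PAC subsampling never share an RNG stream.
# Kept below 2^31 so the result is always a valid R integer seed.
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 131 + ch) %% 1000003
  as.integer((abs(seed) * 7919 + h * 104729 + 17) %% 2147483647)
}

# Evaluate `expr` under a local RNG state; the caller's stream is untouched.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
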