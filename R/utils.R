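# Internal helpers shared across modules.

#' Population standard deviation
#'
#' Standard deviation with the population convention (divide by `n`, not
#' `n - 1`). All mean-plus-SD thresholds in this package use this convention
#' so that cutoffs are exactly reproducible from the stored value vectors.
#'
#' @param x Numeric vector.
#' @return A single non-negative number; `NaN` for empty input.
#' @export
pop_sd <- function(x) {
  sqrt(mean((x - mean(x))^2))
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# .Random.seed is restored afterwards so library code never perturbs user RNG.
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env) else
      suppressWarnings(rm(".Random.seed", envir = env))
  })
  set.seed(seed)
  force(expr)
}

# Stable per-name sub-seeds: independent of the order in which names are
# supplied, so collection-order permutations cannot change results.
derive_seeds <- function(seed, names) {
  stopifnot(!anyDuplicated(names))
  ord <- order(names, method = "radix")
  seeds <- with_seed(seed, sample.int(.Machine$integer.max, length(names)))
  out <- integer(length(names))
  out[ord] <- seeds
  names(out) <- names
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_domain <- function(...) stop(..., call. = FALSE)
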