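#' Derive a reproducible sub-seed from a master seed
#'
#' Every stochastic stage of the workflow (cross-validation partitions,
#' feature-subset evaluations, Monte Carlo resamples, synthetic cohorts) draws
#' its seed from a single master seed through this function, so a whole run is
#' reproducible from one integer while stages stay statistically decoupled.
#'
#' @param seed master seed (single integer-valued number).
#' @param index stream index (single integer-valued number, >= 0).
#' @return A single integer in `[1, 2^31 - 1]`.
#' @examples
#' derive_seed(1, 1)
#' derive_seed(1, 2)
#' @export
derive_seed <- function(seed, index) {
  stopifnot(length(seed) == 1, length(index) == 1, is.finite(seed), is.finite(index))
  m <- 2147483647 # 2^31 - 1; all arithmetic stays exact in doubles (< 2^53)
  s <- as.double(seed) %% m
  as.integer((s * 48271 + 7919 * (as.double(index) %% m)) %% m) + 1L
}

# Evaluate `code` with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards so library functions never clobber user randomness.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
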