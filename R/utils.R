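#' Derive a child seed from a master seed
#'
#' Deterministic splitting rule used to give every stage (truth assignment,
#' count sampling, outlier injection) and every replicate its own RNG stream
#' while keeping a single user-facing seed. The child seed is
#' `(seed * 7919 + stage * 104729 + index) mod (2^31 - 1)`, which stays
#' within R's 32-bit integer range.
#'
#' @param seed master seed (integer).
#' @param stage integer stage code (>= 0).
#' @param index integer replicate/branch index (>= 0).
#' @return an integer usable with [set.seed()].
#' @export
derive_seed <- function(seed, stage = 0L, index = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  m <- 2147483647
  s <- (as.double(seed) %% m) * 7919 + as.double(stage) * 104729 +
    as.double(index)
  as.integer(s %% m)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_msg <- function(...) stop(sprintf(...), call. = FALSE)

assert_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0 || x > 1)
    stop_msg("'%s' must be a single number in [0, 1]", name)
  invisible(x)
}
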