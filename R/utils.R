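#' Derive a per-stage child seed from a global seed
#'
#' One global seed expands into stage-specific seeds by a fixed
#' Lehmer-style derivation so each pipeline stage is independently
#' reproducible. Results stay below 2^31 - 1.
#'
#' @param seed integer global seed.
#' @param stage integer stage index (>= 0).
#' @return an integer seed.
#' @export
child_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  m <- 2147483647
  s <- (abs(as.numeric(seed)) %% m)
  # one multiplicative step per stage offset; 48271 is the MINSTD multiplier
  x <- (s * 48271 + 12345 * (as.numeric(stage) + 1)) %% m
  as.integer(x)
}

clamp_prob <- function(p, lo = 1e-6, hi = 1 - 1e-6) {
  pmin(pmax(p, lo), hi)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

# dense numeric matrix from possibly sparse input
as_dense <- function(m) {
  if (inherits(m, "Matrix")) as.matrix(m) else m
}
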