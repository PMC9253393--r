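#' Derive a per-component random seed
#'
#' Deterministically derives a child seed from a base seed and an index so that
#' every stage and resampling iteration of the pipeline has its own seed while
#' the whole run is reproducible from one integer. Values stay within the
#' 32-bit signed integer range R requires of `set.seed()`.
#'
#' @param seed Base integer seed.
#' @param index Non-negative integer offset (e.g. iteration number).
#' @return A single integer seed.
#' @export
derive_seed <- function(seed, index) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  stopifnot(is.numeric(index), length(index) == 1L, index >= 0)
  as.integer((abs(seed) * 48271 + index * 16807 + 12345) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_bad_arg <- function(...) stop(..., call. = FALSE)

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

#' Lognormal parameters from a median and quartiles
#'
#' Moment-matches a lognormal distribution to a reported median and first/third
#' quartiles: `meanlog = log(median)` and `sdlog` chosen so the interquartile
#' ratio matches (`sdlog = log(q3/q1) / (2 * qnorm(0.75))`). Used to emulate
#' positive, right-skewed laboratory analytes from published summary rows.
#'
#' @param median,q1,q3 Positive reported median and quartiles (q1 < median < q3).
#' @return List with `meanlog` and `sdlog`.
#' @export
lognormal_params_from_quartiles <- function(median, q1, q3) {
  stopifnot(median > 0, q1 > 0, q3 > q1)
  list(meanlog = log(median), sdlog = log(q3 / q1) / (2 * qnorm(0.75)))
}
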