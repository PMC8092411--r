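# internal helpers shared across modules

#' @useDynLib tempomics, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# deterministic child seeds below 2^31, so one study seed drives every
# sub-generator without the streams colliding
child_seed <- function(seed, index) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  (abs(seed) * 48271 + index * 1299709) %% 2147483587
}

# z-score with the population sd (divisor n); errors on constant input
zscore_pop <- function(x) {
  m <- mean(x)
  s <- sqrt(mean((x - m)^2))
  if (s == 0) stop("cannot z-score a constant vector")
  (x - m) / s
}

# trapezoidal integral of y over x
trapz <- function(x, y) {
  n <- length(x)
  sum((y[-1] + y[-n]) / 2 * diff(x))
}

logspace <- function(from, to, n) 10^seq(log10(from), log10(to), length.out = n)

`%||%` <- function(a, b) if (is.null(a)) b else a

stage_log <- function(verbose, ...) {
  if (isTRUE(verbose)) {
    message(format(Sys.time(), "[%Y-%m-%d %H:%M:%S] "), ...)
  }
  invisible(NULL)
}
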