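#' Causal Gaussian-weighted moving average
#'
#' Smooths a series with a trailing (causal) Gaussian kernel spanning the
#' current sample and the `k` previous samples, so no mass leaks backwards in
#' time. Weights are renormalised over the samples actually available, which
#' keeps a constant series exactly constant, including at the left edge.
#'
#' @param x numeric vector, or a matrix smoothed row-wise.
#' @param k number of previous samples included in the window (window length
#'   is `k + 1`).
#' @param sigma kernel standard deviation in samples; default `k / 5`.
#' @return object of the same shape as `x`.
#' @export
smooth_causal_gaussian <- function(x, k, sigma = k / 5) {
  if (is.matrix(x)) {
    return(t(apply(x, 1L, smooth_causal_gaussian, k = k, sigma = sigma)))
  }
  stopifnot(is.numeric(x), k >= 0)
  if (k == 0 || length(x) == 0) return(x)
  lags <- 0:k
  w <- exp(-lags^2 / (2 * max(sigma, 1e-12)^2))
  n <- length(x)
  out <- numeric(n)
  for (i in seq_len(n)) {
    j <- i - lags
    ok <- j >= 1L
    out[i] <- sum(x[j[ok]] * w[ok]) / sum(w[ok])
  }
  out
}

# Events in [a, b), vectorised over windows. Uses a strict half-open
# convention: an event exactly at `a` counts, one exactly at `b` does not.
count_in_windows <- function(times, starts, ends) {
  times <- sort(times)
  vapply(seq_along(starts), function(i) {
    sum(times >= starts[i] & times < ends[i])
  }, integer(1))
}

# Run `expr` under a temporary seed without touching the caller's RNG stream.
with_seed <- function(seed, expr) {
  withr::with_seed(seed, expr)
}

# Derive a vector of sub-seeds from one master seed, each < 2^31.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_input <- function(...) stop(sprintf(...), call. = FALSE)
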