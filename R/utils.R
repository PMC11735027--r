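#' Derive a child seed from a root seed and a named stream
#'
#' Every stochastic stage of the pipeline draws its seed from the run's root
#' seed and a stage label, so stages are reproducible independently of the
#' order in which they execute. The mapping is a small multiplicative hash
#' kept strictly below 2^31 so the result is always a valid R integer seed.
#'
#' @param seed Integer root seed.
#' @param stream Character stage label, or an integer stream index (used by
#'   grid searches to give each grid cell its own stream).
#' @return A single integer seed.
#' @export
derive_seed <- function(seed, stream) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  if (is.character(stream)) {
    h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  } else {
    h <- as.numeric(stream)
  }
  m <- 2147483647  # 2^31 - 1
  s <- (as.numeric(seed) %% m) * 48271 + h * 16807 + 12345
  as.integer(s %% m)
}

#' Gaussian kernel smoothing of a regularly sampled series
#'
#' Smooths a binned rate curve with a discrete Gaussian kernel whose
#' bandwidth (standard deviation) is given in the units of the time axis.
#' The kernel is renormalized at the edges so the smoother preserves a
#' constant input exactly.
#'
#' @param x Numeric vector sampled on a regular grid.
#' @param bandwidth Kernel standard deviation, in time-axis units.
#' @param step Grid spacing, same units as `bandwidth`.
#' @return Smoothed vector, same length as `x`.
#' @keywords internal
gauss_smooth <- function(x, bandwidth, step) {
  stopifnot(bandwidth >= 0, step > 0)
  if (bandwidth == 0) return(x)
  half <- max(1L, ceiling(4 * bandwidth / step))
  k <- stats::dnorm(seq(-half, half) * step, sd = bandwidth)
  n <- length(x)
  out <- numeric(n)
  for (i in seq_len(n)) {
    j <- max(1L, i - half):min(n, i + half)
    w <- k[j - i + half + 1L]
    out[i] <- sum(x[j] * w) / sum(w)
  }
  out
}

# shared input checks
check_scalar <- function(x, name, lower = -Inf, upper = Inf) {
  if (length(x) != 1L || !is.numeric(x) || !is.finite(x))
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  if (x < lower || x > upper)
    stop(sprintf("`%s` must be in [%s, %s]", name, lower, upper), call. = FALSE)
  invisible(x)
}
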