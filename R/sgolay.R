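# Savitzky-Golay smoothing: local least-squares polynomial fits evaluated at
# the window centre. Interior points use a fixed convolution kernel; the
# half-window at each edge refits on the truncated (asymmetric) window, which
# keeps the filter exact on polynomials up to `polyorder` everywhere.

sg_kernel <- function(window, polyorder) {
  h <- (window - 1L) %/% 2L
  x <- seq.int(-h, h)
  A <- outer(x, 0:polyorder, `^`)
  # row of the hat matrix for the centre point (x = 0)
  (solve(crossprod(A), t(A)))[1L, ]
}

#' Savitzky-Golay smoothing of a signal profile
#'
#' Smooths a regularly spaced signal by least-squares polynomial fitting in a
#' sliding window. Polynomials of degree at most `polyorder` are reproduced
#' exactly, including at the edges (where asymmetric windows are refit).
#' `NA` values are not allowed; interpolate or drop gaps first.
#'
#' @param profile numeric vector of signal values on a regular grid.
#' @param window odd window length in points (> `polyorder`), default 51.
#' @param polyorder polynomial order, default 3.
#' @return smoothed numeric vector of the same length.
#' @export
smooth_profile <- function(profile, window = 51L, polyorder = 3L) {
  n <- length(profile)
  window <- as.integer(window)
  if (window %% 2L != 1L) stop("window must be odd")
  if (window <= polyorder) stop("window must exceed polyorder")
  if (window >= n) stop("window (", window, ") must be shorter than the profile (", n, ")")
  if (anyNA(profile)) stop("profile contains NA; handle gaps before smoothing")
  h <- (window - 1L) %/% 2L
  out <- stats::filter(profile, sg_kernel(window, polyorder), sides = 2L)
  out <- as.numeric(out)
  # refit the edge points on their truncated windows
  for (i in c(seq_len(h), seq.int(n - h + 1L, n))) {
    idx <- max(1L, i - h):min(n, i + h)
    x <- idx - i
    A <- outer(x, 0:polyorder, `^`)
    beta <- qr.coef(qr(A), profile[idx])
    out[i] <- beta[1L]
  }
  out
}

#' First derivative of a signal profile
#'
#' Central differences divided by the grid step; one-sided differences at the
#' endpoints.
#'
#' @param profile numeric vector (length >= 2) on a regular grid.
#' @param step grid spacing in bp (default 1).
#' @return numeric vector of the same length, derivative per bp.
#' @export
derivative_profile <- function(profile, step = 1) {
  n <- length(profile)
  if (n < 2L) stop("at least 2 points are required")
  out <- numeric(n)
  out[1] <- (profile[2] - profile[1]) / step
  out[n] <- (profile[n] - profile[n - 1]) / step
  if (n > 2L) {
    out[2:(n - 1)] <- (profile[3:n] - profile[1:(n - 2)]) / (2 * step)
  }
  out
}
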