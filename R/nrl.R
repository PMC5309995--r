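#' Compute the phasogram of start-to-start fragment distances
#'
#' For every ordered fragment pair with `0 < start_j - start_i <= delta`, the
#' frequency of the distance `start_j - start_i` is counted ("leftmost end" =
#' fragment start regardless of strand, the fragments being full-length).
#' Periodic peaks of the phasogram at multiples of the nucleosome repeat
#' length reflect regular nucleosome spacing.
#'
#' @param frags a `fragment_set`.
#' @param delta maximum distance in bp, typically 1000-3000.
#' @return a `phasogram`: list with `counts` (integer vector, `counts[d]` =
#'   number of pairs at distance `d`) and `delta`.
#' @export
compute_phasogram <- function(frags, delta = 1000L) {
  if (delta < 1) stop("delta must be >= 1")
  delta <- as.integer(delta)
  starts <- sort(frags$start)
  n <- length(starts)
  if (n < 2L) {
    counts <- integer(delta)
  } else {
    hi <- findInterval(starts + delta, starts)   # last j with start_j <= start_i + delta
    m <- hi - seq_len(n)
    anchors <- rep.int(seq_len(n), m)
    js <- sequence(m, from = seq_len(n) + 1L)
    d <- starts[js] - starts[anchors]
    counts <- tabulate(d[d >= 1L], nbins = delta)  # d = 0 (duplicate starts) excluded
  }
  structure(list(counts = counts, delta = delta), class = "phasogram")
}

#' @export
print.phasogram <- function(x, ...) {
  cat(sprintf("phasogram: delta %d bp, %.0f pairs\n", x$delta, sum(x$counts)))
  invisible(x)
}

#' Write / read a phasogram as two-column TSV (distance, count)
#'
#' @param phasogram a `phasogram`.
#' @param path file path.
#' @return the path (write) or a `phasogram` (read).
#' @export
write_phasogram <- function(phasogram, path) {
  write_table_auto(data.frame(distance = seq_len(phasogram$delta),
                              count = phasogram$counts), path)
}

#' @rdname write_phasogram
#' @export
read_phasogram <- function(path) {
  dt <- read_table_auto(path)
  delta <- max(as.integer(dt[[1]]))
  counts <- integer(delta)
  counts[as.integer(dt[[1]])] <- as.numeric(dt[[2]])
  structure(list(counts = counts, delta = delta), class = "phasogram")
}

# topographic prominence of a local maximum: height above the higher of the
# two valleys separating it from the nearest taller points (or the ends)
peak_prominence <- function(s, p) {
  n <- length(s)
  left <- if (p > 1L) {
    higher <- which(s[seq_len(p - 1L)] > s[p])
    from <- if (length(higher)) max(higher) else 1L
    min(s[from:(p - 1L)])
  } else s[p]
  right <- if (p < n) {
    higher <- which(s[(p + 1L):n] > s[p]) + p
    to <- if (length(higher)) min(higher) else n
    min(s[(p + 1L):to])
  } else s[p]
  s[p] - max(left, right)
}

#' Detect periodic peaks in a phasogram
#'
#' Counts are Savitzky-Golay smoothed; interior local maxima are filtered by
#' topographic prominence (discarding shallow noise bumps between the
#' periodic peaks), ranked by height and greedily retained subject to a
#' minimum separation; positions are refined by parabolic interpolation on
#' the smoothed curve; and peaks below `exclude_below` (the sub-100-bp
#' duplicate/overlapping-fragment artifact zone) are discarded.
#'
#' @param phasogram a `phasogram`.
#' @param smooth_window Savitzky-Golay window in bp (odd), default 51.
#' @param polyorder Savitzky-Golay polynomial order, default 3.
#' @param min_separation minimum distance between retained peaks, default 100.
#' @param exclude_below discard peaks at distances below this (default 100).
#' @param min_prominence minimum peak prominence as a fraction of the largest
#'   prominence, default 0.1.
#' @return numeric vector of peak positions (bp), ascending; error when fewer
#'   than 2 peaks are found.
#' @export
detect_peaks <- function(phasogram, smooth_window = 51L, polyorder = 3L,
                         min_separation = 100L, exclude_below = 100L,
                         min_prominence = 0.1) {
  y <- phasogram$counts
  if (length(y) == 0L || all(y == 0)) stop("empty phasogram")
  s <- smooth_profile(y, window = smooth_window, polyorder = polyorder)
  n <- length(s)
  i <- 2:(n - 1)
  cand <- i[s[i] > s[i - 1] & s[i] >= s[i + 1]]
  if (length(cand)) {
    prom <- vapply(cand, peak_prominence, numeric(1), s = s)
    cand <- cand[prom >= min_prominence * max(prom)]
  }
  cand <- cand[order(s[cand], decreasing = TRUE)]
  kept <- integer(0)
  for (p in cand) {
    if (all(abs(p - kept) >= min_separation)) kept <- c(kept, p)
  }
  # parabolic sub-bin refinement on the smoothed curve
  pos <- vapply(sort(kept), function(p) {
    denom <- s[p - 1] - 2 * s[p] + s[p + 1]
    if (denom == 0) return(as.numeric(p))
    p + 0.5 * (s[p - 1] - s[p + 1]) / denom
  }, numeric(1))
  pos <- pos[pos >= exclude_below]
  if (length(pos) < 2L) {
    stop("fewer than 2 phasogram peaks found; increase delta or sequencing depth")
  }
  pos
}

#' Fit the nucleosome repeat length from phasogram peak positions
#'
#' Ordinary least squares of peak position against peak index (1, 2, ...):
#' the slope is the nucleosome repeat length (NRL) in bp, with the standard
#' error of the slope as its uncertainty. The intercept is reported but not
#' interpreted.
#'
#' @param peak_positions numeric vector of >= 2 ascending peak positions (bp).
#' @return an `nrl_fit` list: `nrl` (slope, bp), `nrl_err` (SE of the slope,
#'   `NA` for two points), `intercept`, `r_squared`, `peak_positions`.
#' @export
fit_nrl <- function(peak_positions) {
  k <- length(peak_positions)
  if (k < 2L) stop("at least 2 peaks are required to fit the NRL")
  idx <- seq_len(k)
  fit <- stats::lm(peak_positions ~ idx)
  sm <- suppressWarnings(summary(fit))   # exactly collinear peaks are fine
  slope <- unname(stats::coef(fit)[2L])
  if (slope <= 0) stop("non-positive slope: peak positions are not increasing")
  structure(list(nrl = slope,
                 nrl_err = if (k > 2L) sm$coefficients[2L, 2L] else NA_real_,
                 intercept = unname(stats::coef(fit)[1L]),
                 r_squared = sm$r.squared,
                 peak_positions = peak_positions),
            class = "nrl_fit")
}

#' @export
print.nrl_fit <- function(x, ...) {
  cat(sprintf("NRL = %.1f +/- %s bp (%d peaks, R^2 = %.4f)\n", x$nrl,
              if (is.na(x$nrl_err)) "NA" else sprintf("%.1f", x$nrl_err),
              length(x$peak_positions), x$r_squared))
  invisible(x)
}

#' Estimate the NRL from fragments in one call
#'
#' Convenience wrapper: phasogram, peak detection, linear fit.
#'
#' @inheritParams compute_phasogram
#' @inheritParams detect_peaks
#' @return an `nrl_fit`.
#' @export
estimate_nrl <- function(frags, delta = 1000L, smooth_window = 51L,
                         polyorder = 3L, min_separation = 100L) {
  fit_nrl(detect_peaks(compute_phasogram(frags, delta),
                       smooth_window = smooth_window, polyorder = polyorder,
                       min_separation = min_separation))
}
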