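#' Average occupancy tracks across replicates
#'
#' Aligns tracks positionally by window start (a window missing from a
#' replicate is treated as zero coverage, since zero-suppressed `.occ` files
#' encode absence as no coverage) and reports per-window mean, sample standard
#' deviation (n - 1 denominator) and standard error `sd / sqrt(n)`.
#'
#' @param tracks list of two or more `occupancy_track`s with identical window
#'   size (same chromosome assumed).
#' @return a `region_stats` data.frame with columns `chrom`, `start`, `end`,
#'   `mean_occ`, `sd`, `se` and attributes `window_size`, `n_replicates`.
#' @export
average_replicates <- function(tracks) {
  if (length(tracks) < 2L) stop("at least 2 replicate tracks are required")
  ws <- vapply(tracks, attr, integer(1), which = "window_size")
  if (length(unique(ws)) != 1L) stop("replicate tracks have mismatched window sizes")
  w <- ws[1]
  grid <- sort(unique(unlist(lapply(tracks, function(t) t$pos))))
  n <- length(tracks)
  vals <- vapply(tracks, function(t) {
    v <- numeric(length(grid))
    v[match(t$pos, grid)] <- t$value
    v
  }, numeric(length(grid)))
  if (length(grid) == 1L) vals <- matrix(vals, nrow = 1L)
  m <- rowMeans(vals)
  sd <- apply(vals, 1L, stats::sd)
  out <- data.frame(chrom = attr(tracks[[1]], "chrom"), start = grid,
                    end = grid + w, mean_occ = m, sd = sd, se = sd / sqrt(n),
                    stringsAsFactors = FALSE)
  structure(out, class = c("region_stats", "data.frame"),
            window_size = w, n_replicates = n)
}

#' Replicate occupancy statistics straight from fragment sets
#'
#' Convenience pipeline: each replicate fragment set is converted to a
#' windowed occupancy track, depth-normalised with its own read count and
#' data-derived chromosome span, and the replicates are averaged.
#'
#' @param frag_sets list of >= 2 single-chromosome `fragment_set`s
#'   (replicates of one condition).
#' @param window_size window size in bp.
#' @param nuc_size average fragment size for normalisation, default 147.
#' @return a `region_stats` data.frame (see [average_replicates()]).
#' @export
replicate_occupancy_stats <- function(frag_sets, window_size, nuc_size = 147) {
  tracks <- lapply(frag_sets, function(fr) {
    normalize_occupancy(compute_windowed_occupancy(fr, window_size),
                        normalization_params(nuc_size, nrow(fr), chromosome_span(fr)))
  })
  average_replicates(tracks)
}

#' Classify windows as stable, fuzzy, or neither by relative error
#'
#' The relative error of a window is the ratio of the replicate error estimate
#' to the replicate-averaged signal. Windows with relative error below
#' `stable_max` (and occupancy at least `min_occ`) are called stable; windows
#' with relative error above `fuzzy_min` are called fuzzy; all-zero windows
#' are skipped (relative error undefined). Comparisons are strict, matching
#' the conventional cutoffs "< 0.2" for stable and "> 2" for fuzzy.
#'
#' Note that with `error = "se"` (the literal definition, SE/mean) the
#' relative error of non-negative data cannot exceed `sqrt((n - 1) / n)` < 1,
#' so a fuzzy cutoff of 2 can never fire; use `error = "sd"` (the
#' coefficient of variation) when calling fuzzy regions with that cutoff.
#'
#' @param stats a `region_stats` data.frame from [average_replicates()].
#' @param stable_max relative-error upper bound for stable calls (default 0.2).
#' @param fuzzy_min relative-error lower bound for fuzzy calls (default 2).
#' @param min_occ minimum mean occupancy for a stable call (default 0).
#' @param error error estimator in the numerator: `"se"` (standard error,
#'   default) or `"sd"` (standard deviation).
#' @return `stats` minus skipped windows, with added columns `abs_err`,
#'   `rel_err` and `label` (`"stable"`, `"fuzzy"`, `"neither"`).
#' @export
classify_regions <- function(stats, stable_max = 0.2, fuzzy_min = 2,
                             min_occ = 0, error = c("se", "sd")) {
  error <- match.arg(error)
  if (!stable_max < fuzzy_min) stop("stable_max must be below fuzzy_min")
  keep <- stats$mean_occ > 0
  out <- as.data.frame(stats)[keep, , drop = FALSE]
  out$abs_err <- if (error == "se") out$se else out$sd
  out$rel_err <- out$abs_err / out$mean_occ
  out$label <- "neither"
  out$label[out$rel_err > fuzzy_min] <- "fuzzy"
  out$label[out$rel_err < stable_max & out$mean_occ >= min_occ] <- "stable"
  structure(out, class = c("stability_calls", "region_stats", "data.frame"),
            window_size = attr(stats, "window_size"),
            n_replicates = attr(stats, "n_replicates"),
            thresholds = c(stable_max = stable_max, fuzzy_min = fuzzy_min,
                           min_occ = min_occ),
            error = error)
}

#' Write region statistics / stability calls as BED-like TSV
#'
#' Columns: chrom, start, end, mean, abs_err, rel_err and, when present,
#' label.
#'
#' @param stats a `region_stats` or `stability_calls` data.frame.
#' @param path output path (`.gz` compresses).
#' @return the path, invisibly.
#' @export
write_region_stats <- function(stats, path) {
  df <- as.data.frame(stats)
  cols <- intersect(c("chrom", "start", "end", "mean_occ", "abs_err", "rel_err", "label"),
                    names(df))
  write_table_auto(df[, cols, drop = FALSE], path, col.names = TRUE)
}
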