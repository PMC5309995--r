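#' Relative occupancy change between two conditions
#'
#' The bounded statistic `o_diff = 2 * (occ_1 - occ_2) / (occ_1 + occ_2)`,
#' ranging over `[-2, 2]` for non-negative inputs; `|o_diff| = 2` exactly when
#' one condition is zero. Undefined (`NaN`) when both are zero — callers must
#' skip such windows.
#'
#' @param occ_1,occ_2 non-negative occupancy values (vectorised).
#' @return the relative change, condition 1 minus condition 2 orientation.
#' @export
relative_change <- function(occ_1, occ_2) {
  if (any(occ_1 < 0, na.rm = TRUE) || any(occ_2 < 0, na.rm = TRUE)) {
    stop("occupancy values must be non-negative")
  }
  2 * (occ_1 - occ_2) / (occ_1 + occ_2)
}

#' Compare occupancy (or fuzziness) between two conditions
#'
#' Aligns two per-window statistics streams positionally by window start
#' (windows present in only one condition are treated as 0 in the other),
#' computes the relative change of the selected signal column, and emits
#' windows with `|o_diff| >= threshold`, partitioned into gained
#' (`o_diff >= threshold`, condition 1 above condition 2) and lost. Windows
#' where both conditions are zero are skipped.
#'
#' @param stats_1,stats_2 `region_stats` (or `stability_calls`) data.frames
#'   for conditions 1 and 2, same window size.
#' @param signal which column to compare: `"occupancy"` (`mean_occ`) or
#'   `"rel_err"` (fuzziness).
#' @param threshold minimum absolute relative change to report (inclusive),
#'   e.g. 0.99.
#' @return a `diff_regions` data.frame with columns `chrom`, `start`, `end`,
#'   `occ_1`, `occ_2`, `o_diff`, `direction` (`"gained"`/`"lost"`); attribute
#'   `n_skipped` counts both-zero windows.
#' @export
compare_conditions <- function(stats_1, stats_2, signal = c("occupancy", "rel_err"),
                               threshold = 0.99) {
  signal <- match.arg(signal)
  w1 <- attr(stats_1, "window_size"); w2 <- attr(stats_2, "window_size")
  if (!is.null(w1) && !is.null(w2) && w1 != w2) stop("mismatched window sizes")
  col <- if (signal == "occupancy") "mean_occ" else "rel_err"
  grid <- sort(unique(c(stats_1$start, stats_2$start)))
  v1 <- numeric(length(grid)); v1[match(stats_1$start, grid)] <- stats_1[[col]]
  v2 <- numeric(length(grid)); v2[match(stats_2$start, grid)] <- stats_2[[col]]
  both_zero <- v1 == 0 & v2 == 0
  o_diff <- relative_change(v1[!both_zero], v2[!both_zero])
  w <- if (!is.null(w1)) w1 else if (length(grid) > 1L) min(diff(grid)) else 1L
  chrom <- if (nrow(stats_1)) stats_1$chrom[1] else stats_2$chrom[1]
  hit <- abs(o_diff) >= threshold
  g <- grid[!both_zero]
  out <- data.frame(chrom = rep(chrom, length.out = sum(hit)),
                    start = g[hit], end = g[hit] + w,
                    occ_1 = v1[!both_zero][hit], occ_2 = v2[!both_zero][hit],
                    o_diff = o_diff[hit],
                    direction = ifelse(o_diff[hit] >= threshold, "gained", "lost"),
                    stringsAsFactors = FALSE)
  structure(out, class = c("diff_regions", "data.frame"),
            window_size = w, n_skipped = sum(both_zero),
            signal = signal, threshold = threshold)
}

#' Write gained and lost differential regions as two BED-like TSV files
#'
#' @param diff a `diff_regions` data.frame from [compare_conditions()].
#' @param gained_path,lost_path output paths.
#' @return invisibly, a named vector of the two paths.
#' @export
write_diff_regions <- function(diff, gained_path, lost_path) {
  cols <- c("chrom", "start", "end", "occ_1", "occ_2", "o_diff")
  write_table_auto(as.data.frame(diff)[diff$direction == "gained", cols], gained_path,
                   col.names = TRUE)
  write_table_auto(as.data.frame(diff)[diff$direction == "lost", cols], lost_path,
                   col.names = TRUE)
  invisible(c(gained = gained_path, lost = lost_path))
}
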