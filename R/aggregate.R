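#' Build a feature-aligned occupancy profile matrix
#'
#' Extracts, for each anchored feature, the occupancy values on a relative
#' position grid `[-flank, +flank]` (step = track window size) centred on the
#' feature anchor's window. Minus-strand rows are reversed so that position
#' `+x` is downstream of the feature. Positions outside the track are explicit
#' gaps (`NA`); windows inside the track range but zero-suppressed are 0.
#' Features on chromosomes absent from `tracks` are dropped (count reported
#' via the `n_dropped` attribute and a warning).
#'
#' @param tracks a single `occupancy_track` or a named list of tracks keyed by
#'   chromosome.
#' @param features a `feature_set`.
#' @param flank half-width of the grid in bp; must be a multiple of the track
#'   window size.
#' @return a `profile_matrix`: numeric matrix (features x positions) with row
#'   names = feature ids, column names = relative positions, and attributes
#'   `positions`, `window_size`, `n_dropped`.
#' @export
build_profile_matrix <- function(tracks, features, flank) {
  if (inherits(tracks, "occupancy_track")) {
    tracks <- stats::setNames(list(tracks), attr(tracks, "chrom"))
  }
  w <- attr(tracks[[1]], "window_size")
  if (flank %% w != 0L) stop("flank must be a multiple of the window size (", w, ")")
  positions <- seq.int(-flank, flank, by = w)
  keep <- features$chrom %in% names(tracks)
  n_dropped <- sum(!keep)
  if (n_dropped > 0L) {
    warning(sprintf("dropped %d feature(s) on chromosomes absent from tracks", n_dropped))
  }
  feats <- as.data.frame(features)[keep, , drop = FALSE]
  if (nrow(feats) == 0L) stop("no features left after chromosome matching")
  mat <- matrix(NA_real_, nrow = nrow(feats), ncol = length(positions),
                dimnames = list(feats$id, positions))
  for (ch in unique(feats$chrom)) {
    tr <- tracks[[ch]]
    rows <- which(feats$chrom == ch)
    anchor_w <- (feats$anchor[rows] %/% w) * w
    qpos <- outer(anchor_w, positions, `+`)        # rows x positions
    idx <- match(as.vector(qpos), tr$pos)
    val <- tr$value[idx]
    if (nrow(tr)) {
      inside <- as.vector(qpos) >= min(tr$pos) & as.vector(qpos) <= max(tr$pos)
      val[is.na(idx) & inside] <- 0
    }
    block <- matrix(val, nrow = length(rows))
    flip <- feats$strand[rows] == "-"
    block[flip, ] <- block[flip, rev(seq_along(positions)), drop = FALSE]
    mat[rows, ] <- block
  }
  structure(mat, class = c("profile_matrix", "matrix", "array"),
            positions = positions, window_size = w, n_dropped = n_dropped)
}

# rebuild attributes after subsetting a profile matrix's rows
pm_like <- function(mat, template, ...) {
  structure(mat, class = class(template),
            positions = attr(template, "positions"),
            window_size = attr(template, "window_size"), ...)
}

#' Remove artifact rows with suspiciously high occupancy
#'
#' Sequencing artifacts show up as rows whose maximum far exceeds typical
#' occupancy. Rows whose maximum exceeds `max_fold` times the median of all
#' finite matrix values (computed once, on the pre-filter matrix — single
#' pass, hence idempotent) are removed and their ids reported.
#'
#' @param matrix a `profile_matrix`.
#' @param max_fold multiple of the global median above which a row is an
#'   artifact (> 1), default 10.
#' @return the filtered `profile_matrix` with attribute `removed_ids`.
#' @export
filter_artifacts <- function(matrix, max_fold = 10) {
  stopifnot(max_fold > 1)
  med <- stats::median(matrix[is.finite(matrix)])
  row_max <- apply(matrix, 1L, max, na.rm = TRUE)
  bad <- row_max > max_fold * med
  if (all(bad)) stop("artifact filter removed every row; raise max_fold")
  out <- pm_like(matrix[!bad, , drop = FALSE], matrix,
                 removed_ids = rownames(matrix)[bad])
  out
}

#' Aggregate (meta-)profile of a profile matrix
#'
#' Per-position arithmetic mean over non-gap entries, with the per-position
#' number of contributing rows.
#'
#' @param matrix a `profile_matrix` with >= 1 row.
#' @return data.frame with columns `position`, `mean`, `n`.
#' @export
aggregate_profile <- function(matrix) {
  if (nrow(matrix) < 1L) stop("empty matrix")
  data.frame(position = attr(matrix, "positions"),
             mean = colMeans(matrix, na.rm = TRUE),
             n = colSums(!is.na(matrix)),
             row.names = NULL)
}

#' Export / plot helpers for aggregate profiles
#'
#' `write_profile_matrix` writes the matrix as TSV with an id column and
#' position headers; `write_aggregate` writes (position, mean, n);
#' `plot_aggregate` draws the profile with an optional Savitzky-Golay overlay.
#'
#' @param matrix a `profile_matrix`.
#' @param profile data.frame from [aggregate_profile()].
#' @param path output path (`.gz` compresses tables; plots go to PNG).
#' @param smooth_window,polyorder overlay smoothing (`NULL` disables).
#' @return the path, invisibly.
#' @export
write_profile_matrix <- function(matrix, path) {
  df <- data.frame(id = rownames(matrix), as.data.frame(unclass(matrix)),
                   check.names = FALSE)
  write_table_auto(df, path, col.names = TRUE)
}

#' @rdname write_profile_matrix
#' @export
write_aggregate <- function(profile, path) {
  write_table_auto(profile, path, col.names = TRUE)
}

#' @rdname write_profile_matrix
#' @export
plot_aggregate <- function(profile, path = NULL, smooth_window = 51L, polyorder = 3L) {
  if (!is.null(path)) {
    grDevices::png(path, width = 900, height = 600)
    on.exit(grDevices::dev.off())
  }
  graphics::plot(profile$position, profile$mean, type = "l", col = "grey40",
                 xlab = "position relative to anchor (bp)",
                 ylab = "mean occupancy")
  if (!is.null(smooth_window) && smooth_window < nrow(profile)) {
    graphics::lines(profile$position,
                    smooth_profile(profile$mean, smooth_window, polyorder),
                    col = "red", lwd = 2)
  }
  invisible(path)
}
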