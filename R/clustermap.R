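# run code under a fixed seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  force(code)
}

subregion_cols <- function(matrix, subregion) {
  positions <- attr(matrix, "positions")
  if (is.null(subregion)) return(seq_along(positions))
  if (subregion[1] < min(positions) || subregion[2] > max(positions)) {
    stop("subregion outside matrix positions")
  }
  which(positions >= subregion[1] & positions <= subregion[2])
}

row_order_obj <- function(ids, cluster = NULL, provenance = list()) {
  df <- data.frame(id = ids, rank = seq_along(ids),
                   cluster = if (is.null(cluster)) NA_integer_ else cluster,
                   stringsAsFactors = FALSE)
  structure(df, class = c("row_order", "data.frame"), provenance = provenance)
}

#' Sort profile matrix rows by mean signal or external score
#'
#' Descending order of the chosen key with a stable tie-break on the original
#' row order. `mode = "mean_signal"` uses the gap-aware row mean over the
#' `subregion` columns; `mode = "external_score"` uses the supplied scores
#' (e.g. binding-site scores).
#'
#' @param matrix a `profile_matrix`.
#' @param mode `"mean_signal"` or `"external_score"`.
#' @param subregion optional `c(a, b)` relative-bp interval restricting the
#'   mean (default: all positions).
#' @param scores named numeric vector (names = row ids) for
#'   `mode = "external_score"`.
#' @return a `row_order` data.frame (`id`, `rank`, `cluster = NA`).
#' @export
sort_rows <- function(matrix, mode = c("mean_signal", "external_score"),
                      subregion = NULL, scores = NULL) {
  mode <- match.arg(mode)
  ids <- rownames(matrix)
  key <- if (mode == "mean_signal") {
    rowMeans(matrix[, subregion_cols(matrix, subregion), drop = FALSE], na.rm = TRUE)
  } else {
    if (is.null(scores)) stop("scores are required for mode = 'external_score'")
    if (!all(ids %in% names(scores))) stop("scores missing for some row ids")
    scores[ids]
  }
  ord <- order(-key, seq_along(ids))   # stable: ties keep original order
  row_order_obj(ids[ord], provenance = list(mode = mode, subregion = subregion))
}

# k-means++ seeding: spread initial centres with probability proportional to
# squared distance from the nearest centre already chosen.
kmeanspp_init <- function(X, k) {
  n <- nrow(X)
  centers <- integer(k)
  centers[1] <- sample.int(n, 1L)
  d2 <- rowSums(sweep(X, 2L, X[centers[1], ], `-`)^2)
  for (j in seq_len(k - 1L) + 1L) {
    centers[j] <- if (all(d2 == 0)) sample.int(n, 1L) else sample.int(n, 1L, prob = d2)
    d2 <- pmin(d2, rowSums(sweep(X, 2L, X[centers[j], ], `-`)^2))
  }
  X[centers, , drop = FALSE]
}

#' Cluster profile matrix rows with k-means
#'
#' Euclidean k-means (Lloyd) with k-means++ initialisation on the `subregion`
#' columns, deterministic under `seed`. Rows containing gaps in the subregion
#' are dropped with a warning. Clusters are relabelled and ordered by
#' descending cluster-mean signal; rows within a cluster are sorted by
#' descending row mean.
#'
#' @param matrix a `profile_matrix`.
#' @param k number of clusters (>= 2).
#' @param subregion `c(a, b)` relative-bp interval to cluster on (default:
#'   all positions).
#' @param seed integer RNG seed (required for reproducibility).
#' @param row_norm scale each row by its subregion mean before clustering
#'   (shape-based rather than amplitude-based clusters), default `FALSE`.
#' @return a `row_order` with `cluster` labels in `1..k` (1 = highest mean
#'   signal).
#' @export
kmeans_rows <- function(matrix, k, subregion = NULL, seed = 1L, row_norm = FALSE) {
  if (k < 2L) stop("k must be >= 2")
  cols <- subregion_cols(matrix, subregion)
  X <- matrix[, cols, drop = FALSE]
  usable <- rowSums(is.na(X)) == 0L
  if (any(!usable)) {
    warning(sprintf("dropped %d row(s) with gaps in the clustering subregion", sum(!usable)))
  }
  X <- X[usable, , drop = FALSE]
  if (k > nrow(X)) stop("k exceeds the number of usable rows")
  key <- rowMeans(X)
  if (row_norm) {
    sc <- ifelse(key == 0, 1, key)
    X <- X / sc
  }
  km <- with_seed(seed, {
    init <- kmeanspp_init(unname(X), k)
    stats::kmeans(unname(X), centers = init, iter.max = 100L, algorithm = "Lloyd")
  })
  cl <- km$cluster
  # relabel clusters by descending mean signal
  cl_mean <- tapply(key, cl, mean)
  new_lab <- match(cl, as.integer(names(sort(cl_mean, decreasing = TRUE))))
  ord <- order(new_lab, -key, seq_along(key))
  row_order_obj(rownames(X)[ord], cluster = new_lab[ord],
                provenance = list(mode = "kmeans", subregion = subregion,
                                  k = k, seed = seed, row_norm = row_norm))
}

#' Apply a saved row order to another condition's matrix
#'
#' Rearranges the rows of a second matrix (e.g. a different cell state over
#' the same features) to a previously computed order, matching by feature id.
#' Ids absent from the matrix are dropped with a warning count.
#'
#' @param matrix a `profile_matrix`.
#' @param order a `row_order`.
#' @return the reordered `profile_matrix` (attribute `n_unmatched` counts
#'   order ids not found).
#' @export
apply_order <- function(matrix, order) {
  found <- order$id %in% rownames(matrix)
  if (!any(found)) stop("no order ids match the matrix row ids")
  if (any(!found)) {
    warning(sprintf("%d order id(s) absent from the matrix were skipped", sum(!found)))
  }
  pm_like(matrix[order$id[found], , drop = FALSE], matrix,
          n_unmatched = sum(!found))
}

#' Export per-cluster feature BED files
#'
#' Writes one BED file per cluster with the original feature coordinates,
#' score and strand, enabling downstream motif or ontology analysis.
#'
#' @param order a `row_order` with cluster labels.
#' @param features the `feature_set` the matrix was built from.
#' @param out_dir output directory (created if missing).
#' @param prefix file name prefix, default `"cluster"`.
#' @return named character vector of written paths (one per cluster).
#' @export
export_clusters <- function(order, features, out_dir, prefix = "cluster") {
  if (all(is.na(order$cluster))) stop("row order carries no cluster labels")
  missing <- setdiff(order$id, features$id)
  if (length(missing)) {
    stop("unresolvable feature id(s): ", paste(utils::head(missing, 5L), collapse = ", "))
  }
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  feats <- as.data.frame(features)
  rownames(feats) <- feats$id
  labs <- sort(unique(order$cluster))
  paths <- vapply(labs, function(lab) {
    ids <- order$id[order$cluster == lab]
    f <- feats[ids, , drop = FALSE]
    path <- file.path(out_dir, sprintf("%s_%d.bed", prefix, lab))
    write_table_auto(data.frame(chrom = f$chrom, start = f$start, end = f$end,
                                name = f$id,
                                score = ifelse(is.na(f$score), 0, f$score),
                                strand = ifelse(f$strand == "*", ".", f$strand)),
                     path)
    path
  }, character(1))
  names(paths) <- paste0(prefix, "_", labs)
  paths
}

#' Persist / load a row order as TSV (id, rank, cluster)
#'
#' @param order a `row_order`.
#' @param path file path.
#' @return the path (write) or a `row_order` (read).
#' @export
write_row_order <- function(order, path) {
  write_table_auto(as.data.frame(order)[, c("id", "rank", "cluster")], path,
                   col.names = TRUE)
}

#' @rdname write_row_order
#' @export
read_row_order <- function(path) {
  dt <- fread(path, header = TRUE, sep = "\t")
  setDF(dt)
  df <- data.frame(id = as.character(dt$id), rank = as.integer(dt$rank),
                   cluster = suppressWarnings(as.integer(dt$cluster)),
                   stringsAsFactors = FALSE)
  df <- df[order(df$rank), , drop = FALSE]
  structure(df, class = c("row_order", "data.frame"), provenance = list(loaded = path))
}

#' Render a profile matrix as a heatmap
#'
#' Linear colour scale clipped at an upper percentile so isolated artifacts do
#' not flatten the palette; rows drawn top to bottom in matrix order.
#'
#' @param matrix a `profile_matrix` (typically already ordered).
#' @param path optional PNG path; `NULL` draws to the active device.
#' @param clip_quantile upper clipping percentile, default 0.98.
#' @param main plot title.
#' @return the path, invisibly.
#' @export
plot_heatmap <- function(matrix, path = NULL, clip_quantile = 0.98, main = "") {
  vals <- matrix[is.finite(matrix)]
  cap <- stats::quantile(vals, clip_quantile, names = FALSE)
  m <- pmin(unclass(matrix), cap)
  if (!is.null(path)) {
    grDevices::png(path, width = 800, height = 800)
    on.exit(grDevices::dev.off())
  }
  positions <- attr(matrix, "positions")
  graphics::image(x = positions, y = seq_len(nrow(m)), z = t(m[rev(seq_len(nrow(m))), , drop = FALSE]),
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                  xlab = "position relative to anchor (bp)", ylab = "features",
                  main = main, useRaster = TRUE)
  invisible(path)
}
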