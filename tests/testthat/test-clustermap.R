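# two planted row families on a shared position grid
planted_matrix <- function(n_flat = 20, n_peak = 20, seed = 2) {
  set.seed(seed)
  positions <- seq(-500, 500, 100)
  shape <- exp(-(positions / 200)^2)
  flat <- matrix(stats::runif(n_flat * length(positions), 0.2, 0.4), nrow = n_flat)
  peak <- t(replicate(n_peak, 3 * shape + stats::runif(length(positions), 0, 0.2)))
  m <- rbind(flat, peak)
  rownames(m) <- c(sprintf("flat_%d", seq_len(n_flat)),
                   sprintf("peak_%d", seq_len(n_peak)))
  colnames(m) <- positions
  structure(m, class = c("profile_matrix", "matrix", "array"),
            positions = positions, window_size = 100L)
}

test_that("sort_rows orders by key with stable ties and subregion sensitivity", {
  m <- planted_matrix()
  m3 <- m[1:3, , drop = FALSE]
  m3[1, ] <- 3; m3[2, ] <- 1; m3[3, ] <- 2
  pm3 <- structure(m3, class = class(m), positions = attr(m, "positions"),
                   window_size = 100L)
  ord <- sort_rows(pm3)
  expect_equal(ord$id, rownames(m3)[c(1, 3, 2)])
  # all-equal keys keep original order (stable)
  pm_eq <- structure(matrix(1, 4, 11, dimnames = list(letters[1:4], colnames(m))),
                     class = class(m), positions = attr(m, "positions"),
                     window_size = 100L)
  expect_equal(sort_rows(pm_eq)$id, letters[1:4])
  # rows differing only outside +-100 sort differently under narrower subregion
  pm2 <- pm_eq
  pm2["a", 1] <- 50        # boost far-left position of row a only
  expect_equal(sort_rows(pm2)$id[1], "a")
  expect_equal(sort_rows(pm2, subregion = c(-100, 100))$id, letters[1:4])
  # external scores
  sc <- c(a = 1, b = 9, c = 5, d = 2)
  expect_equal(sort_rows(pm_eq, mode = "external_score", scores = sc)$id,
               c("b", "c", "d", "a"))
  expect_error(sort_rows(pm_eq, mode = "external_score"), "scores")
})

test_that("kmeans_rows separates planted families, deterministically under seed", {
  m <- planted_matrix()
  ord <- kmeans_rows(m, k = 2, subregion = c(-500, 500), seed = 17)
  fam <- sub("_.*", "", ord$id)
  # cluster 1 = higher signal = peak family, perfect separation
  expect_true(all(fam[ord$cluster == 1] == "peak"))
  expect_true(all(fam[ord$cluster == 2] == "flat"))
  ord2 <- kmeans_rows(m, k = 2, subregion = c(-500, 500), seed = 17)
  expect_identical(ord, ord2)                          # bitwise reproducible
  expect_setequal(ord$id, rownames(m))                 # permutation, no loss
  expect_error(kmeans_rows(m, k = 1), "k must be")
  expect_error(kmeans_rows(m, k = 100), "usable rows")
  # rows with gaps in the subregion are dropped with a warning
  mg <- m; mg[1, 6] <- NA
  mg <- structure(mg, class = class(m), positions = attr(m, "positions"),
                  window_size = 100L)
  expect_warning(og <- kmeans_rows(mg, 2, seed = 1), "gaps")
  expect_equal(nrow(og), nrow(m) - 1L)
})

test_that("saved orders transfer to another condition by id", {
  m <- planted_matrix(seed = 2)
  m2 <- planted_matrix(seed = 5)                        # same ids, other condition
  ord <- kmeans_rows(m, 2, seed = 17)
  applied <- apply_order(m2, ord)
  expect_equal(rownames(applied), ord$id)               # exact id alignment
  # applying a matrix's own order permutes it
  self <- apply_order(m, ord)
  expect_equal(matrix(self, nrow = nrow(self)), matrix(m[ord$id, ], nrow = nrow(self)))
  # unknown ids skipped with count
  ord_extra <- ord; ord_extra$id[1] <- "ghost"
  expect_warning(ap <- apply_order(m2, ord_extra), "skipped")
  expect_equal(attr(ap, "n_unmatched"), 1L)
  empty_ord <- ord; empty_ord$id <- paste0("x_", seq_along(ord$id))
  expect_error(apply_order(m2, empty_ord), "no order ids")
  # round trip through TSV persistence
  path <- file.path(withr::local_tempdir(), "order.tsv")
  write_row_order(ord, path)
  back <- read_row_order(path)
  expect_equal(back$id, ord$id)
  expect_equal(back$cluster, ord$cluster)
})

test_that("export_clusters writes a per-cluster partition of the features", {
  m <- planted_matrix(n_flat = 6, n_peak = 4, seed = 3)
  feats <- feature_set(chrom = "chrT", anchor = 1000L + 100L * seq_len(10),
                       id = rownames(m), score = seq_len(10),
                       strand = rep(c("+", "-"), 5))
  ord <- kmeans_rows(m, 2, seed = 7)
  out <- withr::local_tempdir()
  paths <- export_clusters(ord, feats, out)
  expect_length(paths, 2L)
  beds <- lapply(paths, read_bed)
  expect_equal(sum(vapply(beds, nrow, integer(1))), 10L)      # partition
  expect_setequal(unlist(lapply(beds, function(b) b$name)), feats$id)
  # unlabelled order errors; unresolvable ids error
  plain <- sort_rows(m)
  expect_error(export_clusters(plain, feats, out), "no cluster labels")
  bad_feats <- feature_set(chrom = "chrT", anchor = 1:3, id = c("a", "b", "c"))
  expect_error(export_clusters(ord, bad_feats, out), "unresolvable")
  # round trip: rebuilding a matrix on one cluster's BED equals the row subset
  tr <- make_track(seq(0L, 2900L, 100L), sqrt(seq(1, 30)), w = 100L)
  full <- build_profile_matrix(tr, feats, 300L)
  ids1 <- ord$id[ord$cluster == 1]
  sub_feats <- read_features(paths[[1]])
  sub <- build_profile_matrix(tr, sub_feats, 300L)
  expect_equal(unname(sub[ids1, ]), unname(full[ids1, ]))
})
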