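test_that("Savitzky-Golay smoothing reproduces low-order polynomials exactly", {
  x <- seq_len(200)
  expect_equal(smooth_profile(rep(3.5, 200)), rep(3.5, 200))
  ramp <- 0.3 * x + 2
  expect_equal(smooth_profile(ramp), ramp)
  cubic <- 1e-4 * x^3 - 0.02 * x^2 + x
  expect_equal(smooth_profile(cubic, 21, 3), cubic)
  # noise reduction on a sine
  set.seed(9)
  clean <- sin(2 * pi * x / 95)
  noisy <- clean + stats::rnorm(200, 0, 0.3)
  sm <- smooth_profile(noisy, 51, 3)
  expect_lt(sqrt(mean((sm - clean)^2)), sqrt(mean((noisy - clean)^2)))
  expect_error(smooth_profile(1:10, 11), "shorter")
  expect_error(smooth_profile(1:10, 4), "odd")
})

test_that("derivative_profile differentiates with correct scaling", {
  expect_equal(derivative_profile(rep(2, 10)), rep(0, 10))
  expect_equal(derivative_profile(3 * (1:10), step = 1), rep(3, 10))
  x <- seq(0, 1900, by = 10)
  y <- sin(2 * pi * x / 190)
  dy <- derivative_profile(y, step = 10)
  expect_equal(dy[2:(length(x) - 1)],
               (2 * pi / 190) * cos(2 * pi * x[2:(length(x) - 1)] / 190),
               tolerance = 0.02)
  expect_error(derivative_profile(1), "2 points")
})

test_that("profile matrix rows align on anchors with strand flipping and gaps", {
  tr <- make_track(seq(0L, 900L, 100L), as.numeric(1:10), w = 100L)
  feats <- feature_set(chrom = "chrT", anchor = c(450L, 450L, 50L),
                       strand = c("+", "-", "+"), id = c("p", "m", "edge"))
  mat <- build_profile_matrix(tr, feats, flank = 200L)
  expect_equal(dim(mat), c(3L, 5L))
  expect_equal(unname(mat["p", ]), c(3, 4, 5, 6, 7))       # extract around 400
  expect_equal(unname(mat["m", ]), rev(c(3, 4, 5, 6, 7)))  # minus strand reversed
  expect_equal(unname(mat["edge", ]), c(NA, NA, 1, 2, 3))  # leading gaps

  # double flip is identity
  feats2 <- feature_set(chrom = "chrT", anchor = 450L, strand = "-", id = "m2")
  m1 <- build_profile_matrix(tr, feats2, 200L)
  expect_equal(unname(m1[1, rev(seq_len(5))]), unname(mat["p", ]))

  # features on unknown chromosomes are dropped with a warning
  feats3 <- feature_set(chrom = c("chrT", "chrX"), anchor = c(450L, 450L),
                        id = c("a", "b"))
  expect_warning(m3 <- build_profile_matrix(tr, feats3, 200L), "dropped 1")
  expect_equal(rownames(m3), "a")
  expect_error(build_profile_matrix(tr, feats, flank = 250L), "multiple")
})

test_that("artifact filter removes spike rows against the pre-filter median", {
  set.seed(12)
  base <- matrix(stats::runif(100 * 11, 0.8, 1.2), nrow = 100)
  base[7, 6] <- 1000
  mat <- structure(base, dimnames = list(sprintf("r%d", 1:100), seq(-500, 500, 100)),
                   class = c("profile_matrix", "matrix", "array"),
                   positions = seq(-500, 500, 100), window_size = 100L)
  filt <- filter_artifacts(mat, max_fold = 10)
  expect_equal(attr(filt, "removed_ids"), "r7")
  expect_equal(nrow(filt), 99L)
  # homogeneous matrix untouched; huge max_fold is identity
  expect_length(attr(filter_artifacts(mat, max_fold = 1e6), "removed_ids"), 0L)
  # single-pass semantics: re-filtering the filtered matrix removes nothing here
  expect_length(attr(filter_artifacts(filt, max_fold = 10), "removed_ids"), 0L)
})

test_that("aggregate profile is a gap-aware mean with row counts", {
  m <- structure(rbind(a = c(1, 2, 3), b = c(3, NA, 5)),
                 class = c("profile_matrix", "matrix", "array"),
                 positions = c(-100, 0, 100), window_size = 100L)
  agg <- aggregate_profile(m)
  expect_equal(agg$mean, c(2, 2, 4))
  expect_equal(agg$n, c(2L, 1L, 2L))
  # identical rows aggregate to the row
  mm <- structure(rbind(a = c(1, 2, 3), b = c(1, 2, 3)),
                  class = c("profile_matrix", "matrix", "array"),
                  positions = c(-100, 0, 100), window_size = 100L)
  expect_equal(aggregate_profile(mm)$mean, c(1, 2, 3))
  # row-partition consistency (gap-aware weights)
  set.seed(4)
  big <- matrix(stats::runif(50 * 5), nrow = 50)
  big[sample(length(big), 30)] <- NA
  pm <- structure(big, dimnames = list(sprintf("r%d", 1:50), seq(-200, 200, 100)),
                  class = c("profile_matrix", "matrix", "array"),
                  positions = seq(-200, 200, 100), window_size = 100L)
  whole <- aggregate_profile(pm)
  p1 <- aggregate_profile(pm[1:20, , drop = FALSE] |> (\(m) structure(m,
        class = class(pm), positions = attr(pm, "positions"),
        window_size = 100L))())
  p2 <- aggregate_profile(pm[21:50, , drop = FALSE] |> (\(m) structure(m,
        class = class(pm), positions = attr(pm, "positions"),
        window_size = 100L))())
  m1 <- ifelse(p1$n == 0, 0, p1$mean)   # n = 0 contributes nothing
  m2 <- ifelse(p2$n == 0, 0, p2$mean)
  recombined <- (m1 * p1$n + m2 * p2$n) / (p1$n + p2$n)
  expect_equal(whole$mean, recombined)
})
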