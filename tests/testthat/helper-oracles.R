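# Independent brute-force oracles, kept deliberately naive and separate from
# the implementation paths they check.

# per-base coverage by looping over fragments and bases
oracle_coverage <- function(frags, span_end = max(frags$end)) {
  cov <- integer(span_end)
  for (i in seq_len(nrow(frags))) {
    idx <- (frags$start[i] + 1L):frags$end[i]   # 1-based over 0-based bp
    cov[idx] <- cov[idx] + 1L
  }
  cov
}

# windowed means from the oracle coverage, dividing by window_size always
oracle_windowed <- function(frags, w) {
  cov <- oracle_coverage(frags)
  starts <- seq.int(0L, length(cov) - 1L, by = w)
  vals <- vapply(starts, function(s) {
    sum(cov[(s + 1L):min(s + w, length(cov))]) / w
  }, numeric(1))
  list(pos = starts, value = vals)
}

# O(n^2) enumeration of start-to-start distances
oracle_phasogram <- function(starts, delta) {
  counts <- integer(delta)
  n <- length(starts)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      d <- starts[j] - starts[i]
      if (d >= 1 && d <= delta) counts[d] <- counts[d] + 1L
    }
  }
  counts
}

# random fragment fixture on one chromosome
random_frags <- function(n, span = 10000L, max_len = 250L, chrom = "chrT") {
  start <- sample.int(span, n, replace = TRUE) - 1L
  len <- sample.int(max_len, n, replace = TRUE)
  fragment_set(data.frame(chrom = chrom, start = start, end = start + len,
                          strand = sample(c("+", "-"), n, replace = TRUE)))
}

# quick track constructor for positional tests
make_track <- function(pos, value, w = 100L, chrom = "chrT", normalized = FALSE) {
  occupancy_track(pos, value, chrom = chrom, window_size = w, normalized = normalized)
}

# truth label of window starts against a truth BED (NA = unlabelled)
truth_label <- function(pos, truth) {
  l <- rep(NA_character_, length(pos))
  for (i in seq_len(nrow(truth))) {
    hit <- pos >= truth$start[i] & pos < truth$end[i]
    l[hit] <- truth$label[i]
  }
  l
}
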