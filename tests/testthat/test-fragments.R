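test_that("single-end extension is strand-specific, clamped and count-conserving", {
  reads <- fragment_set(data.frame(
    chrom = "chr1",
    start = c(100L, 500L, 10L, 700L),
    end   = c(136L, 536L, 46L, 736L),
    strand = c("+", "-", "-", "*")))
  expect_warning(ext <- extend_single_end(reads, 147), "unknown strand")
  expect_equal(attr(ext, "n_rejected"), 1L)
  expect_equal(nrow(ext), 3L)                       # count conserved minus rejects
  expect_equal(c(ext$start[1], ext$end[1]), c(100L, 247L))   # plus: [s, s+L)
  expect_equal(c(ext$start[2], ext$end[2]), c(389L, 536L))   # minus: [e-L, e)
  expect_equal(c(ext$start[3], ext$end[3]), c(0L, 46L))      # clamped at origin
  expect_equal(attr(ext, "n_clamped"), 1L)
})

test_that("paired-end merging spans mate extremes and is order-invariant", {
  pe <- fragment_set(data.frame(chrom = "chr1",
                                start = c(100L, 220L), end = c(136L, 256L),
                                strand = "*"))
  m <- merge_paired_end(pe)
  expect_equal(nrow(m), 1L)
  expect_equal(c(m$start, m$end), c(100L, 256L))
  swapped <- pe[2:1, ]
  m2 <- merge_paired_end(fragment_set(as.data.frame(swapped)))
  expect_equal(c(m2$start, m2$end), c(100L, 256L))

  odd <- fragment_set(data.frame(chrom = "chr1", start = c(1L, 2L, 3L),
                                 end = c(10L, 12L, 13L), strand = "*"))
  expect_error(merge_paired_end(odd), "odd number")

  cross <- fragment_set(data.frame(chrom = c("chr1", "chr2"),
                                   start = c(1L, 5L), end = c(10L, 15L), strand = "*"))
  expect_warning(m3 <- merge_paired_end(cross), "different chromosomes")
  expect_equal(nrow(m3), 0L)
  expect_equal(attr(m3, "n_skipped"), 1L)
})

test_that("fragment length estimation recovers the truth by cross-correlation", {
  # two reads forming one fragment: + start 100, - end 250 -> 150
  tiny <- fragment_set(data.frame(chrom = "c", start = c(100L, 214L),
                                  end = c(136L, 250L), strand = c("+", "-")))
  expect_equal(estimate_fragment_length(tiny, 400), 150L)

  # positioned fragments of true length ~147, sequenced 36 bp from either end;
  # plus-start and minus-end densities share the nucleosome positions
  model <- array_model(chrom_length = 2e5, nrl = 190, jitter_sd = 5,
                       frag_len = 147, frag_len_sd = 2, depth = 10)
  frags <- simulate_array_reads(model, seed = 19)
  reads <- fragment_set(data.frame(
    chrom = frags$chrom,
    start = ifelse(frags$strand == "+", frags$start, frags$end - 36L),
    end   = ifelse(frags$strand == "+", frags$start + 36L, frags$end),
    strand = frags$strand))
  est <- estimate_fragment_length(reads, 250)
  expect_gte(est, 145L); expect_lte(est, 149L)

  plus_only <- fragment_set(data.frame(chrom = "c", start = 1:5,
                                       end = 2:6, strand = "+"))
  expect_error(estimate_fragment_length(plus_only), "both strands")
})

test_that("split_by_chromosome partitions records, preserving order and codecs", {
  df <- data.frame(chrom = c(rep("chr1", 5), rep("chr2", 3)),
                   start = c(10L, 5L, 30L, 2L, 50L, 7L, 3L, 90L),
                   end   = c(20L, 15L, 40L, 12L, 60L, 17L, 13L, 100L),
                   strand = "+")
  frags <- fragment_set(df)
  out1 <- withr::local_tempdir()
  paths <- split_by_chromosome(frags, out1, gzip = FALSE)
  expect_setequal(names(paths), c("chr1", "chr2"))
  c1 <- read_bed(paths[["chr1"]]); c2 <- read_bed(paths[["chr2"]])
  expect_equal(nrow(c1), 5L); expect_equal(nrow(c2), 3L)
  expect_equal(c1$start, df$start[df$chrom == "chr1"])     # original order kept
  expect_equal(nrow(c1) + nrow(c2), nrow(frags))           # partition

  # gzipped input gives the identical partition
  gz <- file.path(withr::local_tempdir(), "in.bed.gz")
  write_bed(frags, gz)
  expect_true(nucleotool:::is_gzipped(gz))
  out2 <- withr::local_tempdir()
  paths_gz <- split_by_chromosome(gz, out2)
  g1 <- read_bed(paths_gz[["chr1"]])
  expect_equal(as.data.frame(g1)[c("chrom", "start", "end")],
               as.data.frame(c1)[c("chrom", "start", "end")])

  empty <- fragment_set(data.frame(chrom = character(), start = integer(),
                                   end = integer(), strand = character()))
  expect_warning(res <- split_by_chromosome(empty, withr::local_tempdir()), "empty")
  expect_length(res, 0L)
})

test_that("fragment_set validates invariants", {
  expect_error(fragment_set(data.frame(chrom = "c", start = -1L, end = 5L)), ">= 0")
  expect_error(fragment_set(data.frame(chrom = "c", start = 5L, end = 5L)), "exceed")
  expect_error(fragment_set(data.frame(chrom = "c", start = 1L, end = 5L,
                                       strand = "x")), "strand")
  fs <- fragment_set(data.frame(chrom = "c", start = c(100L, 900L),
                                end = c(250L, 1050L)))
  expect_equal(fragment_count(fs), 2L)
  expect_equal(unname(fragment_span(fs)), c(100L, 1050L))
})
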