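#' @importFrom data.table fread fwrite setDF setDT :=
#' @importFrom utils head tail
NULL

# Gzip magic bytes are 0x1f 0x8b; sniff rather than trust the extension so that
# mislabelled files still parse ("gzip transparency").
is_gzipped <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", n = 2L)
  length(magic) == 2L && magic[1] == as.raw(0x1f) && magic[2] == as.raw(0x8b)
}

# Read a whitespace/tab-delimited text table, plain or gzipped, no header.
read_table_auto <- function(path, ...) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is_gzipped(path)) {
    # fread needs R.utils for gz; decompress through a connection instead.
    lines <- readLines(gzfile(path))
    if (length(lines) == 0L) return(data.frame())
    dt <- fread(text = lines, header = FALSE, sep = "\t", ...)
  } else {
    if (file.size(path) == 0L) return(data.frame())
    dt <- fread(file = path, header = FALSE, sep = "\t", ...)
  }
  setDF(dt)
  dt
}

# Write a data.frame as TSV; gzip if the path ends in .gz.
write_table_auto <- function(df, path, col.names = FALSE) {
  compress <- if (grepl("\\.gz$", path)) "gzip" else "none"
  fwrite(df, path, sep = "\t", col.names = col.names, compress = compress)
  invisible(path)
}

#' Read mapped reads or fragments from a BED file
#'
#' Accepts BED3+ (chrom, start, end and optionally name, score, strand),
#' plain or gzip-compressed (detected by magic bytes, not extension).
#' Coordinates are 0-based half-open throughout the package.
#'
#' @param path path to a BED or BED.gz file.
#' @return a `fragment_set` data.frame with columns `chrom`, `start`, `end`,
#'   `strand` (one of `"+"`, `"-"`, `"*"` for unknown) and, when present in
#'   the input, `name` and `score`.
#' @export
read_bed <- function(path) {
  dt <- read_table_auto(path)
  if (nrow(dt) == 0L) {
    return(fragment_set(data.frame(chrom = character(), start = integer(),
                                   end = integer(), strand = character())))
  }
  if (ncol(dt) < 3L) stop("BED file needs at least 3 columns: ", path)
  out <- data.frame(chrom = as.character(dt[[1]]),
                    start = as.integer(dt[[2]]),
                    end   = as.integer(dt[[3]]),
                    stringsAsFactors = FALSE)
  if (ncol(dt) >= 4L) out$name  <- as.character(dt[[4]])
  if (ncol(dt) >= 5L) out$score <- suppressWarnings(as.numeric(dt[[5]]))
  out$strand <- if (ncol(dt) >= 6L) {
    s <- as.character(dt[[6]])
    ifelse(s %in% c("+", "-"), s, "*")
  } else "*"
  fragment_set(out)
}

#' Write a fragment set as BED
#'
#' @param frags a `fragment_set` (or BED-like data.frame).
#' @param path output path; a `.gz` suffix triggers gzip compression.
#' @return the path, invisibly.
#' @export
write_bed <- function(frags, path) {
  df <- as.data.frame(frags)
  cols <- data.frame(chrom = df$chrom, start = df$start, end = df$end)
  has_strand <- !is.null(df$strand) && any(df$strand != "*")
  if (has_strand || !is.null(df$name) || !is.null(df$score)) {
    cols$name   <- if (is.null(df$name)) "." else df$name
    cols$score  <- if (is.null(df$score)) 0 else df$score
    cols$strand <- if (is.null(df$strand)) "*" else df$strand
  }
  write_table_auto(cols, path)
}

#' Read an occupancy track from a two-column `.occ` file
#'
#' The `.occ` format has two tab-separated columns: window start (bp, 0-based)
#' and signal value. Gzip input is detected automatically.
#'
#' @param path path to `.occ` or `.occ.gz`.
#' @param chrom chromosome label to attach (the format itself is per-chromosome
#'   and carries no chrom column).
#' @param window_size window size in bp; if `NULL`, inferred from the smallest
#'   positive gap between window starts (1 for a single-row track).
#' @return an `occupancy_track`.
#' @export
read_occ <- function(path, chrom = "chr", window_size = NULL) {
  dt <- read_table_auto(path)
  if (nrow(dt) == 0L) {
    return(occupancy_track(integer(), numeric(), chrom = chrom,
                           window_size = if (is.null(window_size)) 1L else window_size))
  }
  pos <- as.integer(dt[[1]])
  val <- as.numeric(dt[[2]])
  if (is.null(window_size)) {
    gaps <- diff(sort(unique(pos)))
    window_size <- if (length(gaps)) min(gaps) else 1L
  }
  occupancy_track(pos, val, chrom = chrom, window_size = as.integer(window_size))
}

#' Write an occupancy track to a two-column `.occ` file
#'
#' Values are printed with 4 decimal places. Zero-valued windows are written by
#' default so that downstream alignment can be positional.
#'
#' @param track an `occupancy_track`.
#' @param path output path; `.gz` suffix compresses.
#' @param keep_zeros write zero-valued windows (default `TRUE`).
#' @return the path, invisibly.
#' @export
write_occ <- function(track, path, keep_zeros = TRUE) {
  df <- as.data.frame(track)
  if (!keep_zeros) df <- df[df$value != 0, , drop = FALSE]
  out <- data.frame(pos = df$pos, value = sprintf("%.4f", df$value))
  write_table_auto(out, path)
}

#' Read an anchored feature set from a BED6-like file
#'
#' Interval features are reduced to point anchors at
#' `floor((start + end) / 2)`. Column 4 supplies ids (generated when absent or
#' duplicated would be an error), column 5 a numeric score, column 6 strand.
#'
#' @param path path to a BED file, plain or gzipped.
#' @return a `feature_set` data.frame with columns `chrom`, `anchor`, `strand`,
#'   `id`, `score`, `start`, `end`.
#' @export
read_features <- function(path) {
  bed <- read_bed(path)
  df <- as.data.frame(bed)
  ids <- if (!is.null(df$name) && !anyDuplicated(df$name)) df$name
         else sprintf("feature_%d", seq_len(nrow(df)))
  feature_set(chrom = df$chrom, anchor = (df$start + df$end) %/% 2L,
              strand = df$strand, id = ids,
              score = if (is.null(df$score)) rep(NA_real_, nrow(df)) else df$score,
              start = df$start, end = df$end)
}

#' Construct a feature set
#'
#' @param chrom,anchor,strand,id,score,start,end vectors of equal length;
#'   `strand` defaults to unknown, `score` to `NA`, and `start`/`end` to a
#'   1-bp interval at the anchor.
#' @return a `feature_set` data.frame.
#' @export
feature_set <- function(chrom, anchor, strand = NULL, id = NULL, score = NULL,
                        start = NULL, end = NULL) {
  n <- length(anchor)
  strand <- if (is.null(strand)) rep("*", n) else ifelse(strand %in% c("+", "-"), strand, "*")
  id <- if (is.null(id)) sprintf("feature_%d", seq_len(n)) else as.character(id)
  if (anyDuplicated(id)) stop("feature ids must be unique")
  if (any(anchor < 0)) stop("feature anchors must be >= 0")
  df <- data.frame(chrom = as.character(chrom), anchor = as.integer(anchor),
                   strand = strand, id = id,
                   score = if (is.null(score)) NA_real_ else as.numeric(score),
                   start = if (is.null(start)) as.integer(anchor) else as.integer(start),
                   end = if (is.null(end)) as.integer(anchor) + 1L else as.integer(end),
                   stringsAsFactors = FALSE)
  class(df) <- c("feature_set", "data.frame")
  df
}
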