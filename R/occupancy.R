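#' Construct an occupancy track
#'
#' An occupancy track stores one chromosome's windowed signal as
#' `(window_start, value)` pairs. Window starts are multiples of the window
#' size and strictly increasing; values are non-negative. Tracks written with
#' [write_occ()] keep zero-valued windows by default so that window alignment
#' across files is positional.
#'
#' @param pos integer vector of window starts (bp, 0-based).
#' @param value numeric vector of signal values (>= 0).
#' @param chrom chromosome name.
#' @param window_size window size in bp (>= 1).
#' @param normalized whether values are depth-normalised (see
#'   [normalize_occupancy()]).
#' @return an `occupancy_track` (data.frame subclass with attributes `chrom`,
#'   `window_size`, `normalized`).
#' @export
occupancy_track <- function(pos, value, chrom = "chr", window_size = 1L,
                            normalized = FALSE) {
  stopifnot(window_size >= 1, length(pos) == length(value))
  pos <- as.integer(pos)
  if (length(pos)) {
    if (any(pos %% window_size != 0L)) stop("window starts must be multiples of window_size")
    if (is.unsorted(pos, strictly = TRUE)) stop("window starts must be strictly increasing")
    if (any(value < 0)) stop("occupancy values must be non-negative")
  }
  df <- data.frame(pos = pos, value = as.numeric(value))
  structure(df, class = c("occupancy_track", "data.frame"),
            chrom = chrom, window_size = as.integer(window_size),
            normalized = normalized)
}

#' @export
print.occupancy_track <- function(x, ...) {
  cat(sprintf("occupancy_track: %s, window %d bp, %d windows%s\n",
              attr(x, "chrom"), attr(x, "window_size"), nrow(x),
              if (isTRUE(attr(x, "normalized"))) ", normalized" else ""))
  if (nrow(x)) print(utils::head(as.data.frame(x)))
  invisible(x)
}

# per-bp coverage of a single-chromosome fragment set over [0, span_end),
# via a difference array (exact, O(span)).
per_base_coverage <- function(frags) {
  span_end <- max(frags$end)
  n_start <- tabulate(frags$start + 1L, nbins = span_end)  # starts at p (0-based)
  n_end <- tabulate(frags$end, nbins = span_end)           # half-open: drop at p = end
  # coverage[p+1] = #frags with start <= p < end
  cumsum(n_start - c(0L, n_end[-span_end]))
}

#' Compute a windowed occupancy track from fragments
#'
#' Per-bp occupancy is the number of fragments covering each base; the window
#' value is the summed covered bases in the window divided by `window_size`
#' (so that `sum(value) * window_size` equals the total fragment length —
#' exact conservation). Windows tile `[0, span_end)`; zero-valued windows are
#' retained.
#'
#' @param frags a single-chromosome `fragment_set`.
#' @param window_size window size in bp (>= 1). `window_size = 1` yields
#'   per-bp coverage exactly.
#' @return a raw `occupancy_track`.
#' @export
compute_windowed_occupancy <- function(frags, window_size) {
  stopifnot(window_size >= 1)
  window_size <- as.integer(window_size)
  if (nrow(frags) == 0L) {
    warning("empty fragment set: returning empty track")
    return(occupancy_track(integer(), numeric(), window_size = window_size))
  }
  if (length(unique(frags$chrom)) > 1L) {
    stop("fragments span multiple chromosomes; split_by_chromosome() first")
  }
  cov <- per_base_coverage(frags)
  span_end <- length(cov)
  w_starts <- seq.int(0L, span_end - 1L, by = window_size)
  cs <- c(0, cumsum(cov))
  vals <- (cs[pmin(w_starts + window_size, span_end) + 1L] - cs[w_starts + 1L]) / window_size
  occupancy_track(w_starts, vals, chrom = frags$chrom[1], window_size = window_size)
}

#' Depth-normalisation parameters for an occupancy track
#'
#' Bundles the three quantities in the normalisation
#' `O_N = <O_R> / (nuc_size * N_R / chr_length)`:
#' the average fragment size `nuc_size`, the read count `N_R`, and the
#' mappable chromosome length `chr_length`.
#'
#' @param nuc_size average nucleosome fragment size in bp (> 0).
#' @param n_reads number of reads N_R in the input (> 0).
#' @param chr_length mappable chromosome length in bp (> 0), e.g. from
#'   [chromosome_span()].
#' @return a `normalization_params` list.
#' @export
normalization_params <- function(nuc_size, n_reads, chr_length) {
  stopifnot(nuc_size > 0, n_reads > 0, chr_length > 0)
  structure(list(nuc_size = nuc_size, n_reads = n_reads, chr_length = chr_length),
            class = "normalization_params")
}

#' Normalise an occupancy track by sequencing depth
#'
#' Divides every window value by the expected per-bp coverage
#' `nuc_size * N_R / chr_length`, so that a track at exactly the genome-wide
#' average density has normalised occupancy 1 everywhere.
#'
#' @param track a raw `occupancy_track`.
#' @param params a `normalization_params`.
#' @return the normalised `occupancy_track` (`normalized` attribute set).
#' @export
normalize_occupancy <- function(track, params) {
  stopifnot(inherits(params, "normalization_params"))
  if (isTRUE(attr(track, "normalized"))) warning("track is already normalized")
  denom <- params$nuc_size * params$n_reads / params$chr_length
  occupancy_track(track$pos, track$value / denom, chrom = attr(track, "chrom"),
                  window_size = attr(track, "window_size"), normalized = TRUE)
}

#' Mappable chromosome span of a fragment set
#'
#' `chr_length` for normalisation, operationalised as the data-supported span:
#' maximum fragment end minus minimum fragment start. This excludes unmappable
#' chromosome ends, which carry no fragments.
#'
#' @param frags a non-empty `fragment_set`.
#' @return span in bp.
#' @export
chromosome_span <- function(frags) {
  sp <- fragment_span(frags)
  unname(sp["span_end"] - sp["span_start"])
}

#' Extract a sub-region of an occupancy track
#'
#' Returns exactly the windows whose start lies in `[from, to)`, preserving
#' values bit-exactly.
#'
#' @param track an `occupancy_track`.
#' @param from,to half-open genomic interval bounds in bp (`from < to`).
#' @return an `occupancy_track` restricted to the interval (empty, with a
#'   warning, when no window start falls inside).
#' @export
extract_region <- function(track, from, to) {
  stopifnot(from < to)
  keep <- track$pos >= from & track$pos < to
  if (!any(keep)) warning("no window starts within [", from, ",", to, ")")
  occupancy_track(track$pos[keep], track$value[keep], chrom = attr(track, "chrom"),
                  window_size = attr(track, "window_size"),
                  normalized = attr(track, "normalized"))
}

#' Convert per-cytosine methylation calls to an occupancy-like track
#'
#' Cytosines whose methylation fraction is at or above the threshold are
#' counted as 1-bp unit events; windowed density is then computed as for
#' fragments, making methylation tracks directly comparable with occupancy
#' tracks. Records with fractions outside `[0, 1]` are rejected with a
#' warning.
#'
#' @param calls data.frame with columns `chrom`, `pos` (0-based bp) and
#'   `meth_fraction` in `[0, 1]`; or a path to a 3+-column TSV in that layout.
#' @param threshold minimum methylation fraction to count a cytosine
#'   (`threshold = 0` counts every cytosine).
#' @param window_size window size in bp.
#' @return an `occupancy_track` of methylated-cytosine density per bp.
#' @export
methylation_to_track <- function(calls, threshold = 0.5, window_size = 100L) {
  if (is.character(calls)) {
    dt <- read_table_auto(calls)
    calls <- data.frame(chrom = as.character(dt[[1]]), pos = as.integer(dt[[2]]),
                        meth_fraction = as.numeric(dt[[3]]))
  }
  bad <- calls$meth_fraction < 0 | calls$meth_fraction > 1 | is.na(calls$meth_fraction)
  if (any(bad)) {
    warning(sprintf("rejected %d record(s) with methylation fraction outside [0,1]", sum(bad)))
    calls <- calls[!bad, , drop = FALSE]
  }
  hits <- calls[calls$meth_fraction >= threshold, , drop = FALSE]
  if (nrow(hits) == 0L) {
    # all-zero track over the span of all (valid) input cytosines
    if (nrow(calls) == 0L) return(occupancy_track(integer(), numeric(), window_size = window_size))
    w_starts <- seq.int(0L, max(calls$pos), by = window_size)
    return(occupancy_track(w_starts, numeric(length(w_starts)),
                           chrom = calls$chrom[1], window_size = as.integer(window_size)))
  }
  events <- fragment_set(data.frame(chrom = hits$chrom, start = hits$pos,
                                    end = hits$pos + 1L, strand = "*"))
  compute_windowed_occupancy(events, window_size)
}
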