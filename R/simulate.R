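#' Nucleosome-array read simulation model
#'
#' Describes a regularly spaced nucleosome array on one synthetic chromosome:
#' dyads on a lattice with spacing `nrl` and Gaussian positional jitter,
#' sampled with a per-nucleosome occupancy probability, each yielding `depth`
#' sequenced fragments of Gaussian-distributed length centred on the dyad.
#' Defaults echo the mammalian scale: 147 bp core particle, NRL ~190 bp,
#' ~20 bp positional jitter.
#'
#' @param chrom chromosome name, default `"chrSim"`.
#' @param chrom_length chromosome length in bp.
#' @param nrl true nucleosome repeat length (dyad lattice spacing), bp.
#' @param jitter_sd SD of dyad positional noise, bp.
#' @param frag_len,frag_len_sd mean and SD of fragment length, bp.
#' @param depth fragments sequenced per sampled dyad.
#' @param occupancy_prob probability that a dyad position is occupied.
#' @return an `array_model` list.
#' @export
array_model <- function(chrom = "chrSim", chrom_length = 2e6, nrl = 190,
                        jitter_sd = 20, frag_len = 147, frag_len_sd = 3,
                        depth = 5, occupancy_prob = 1) {
  stopifnot(nrl > 0, chrom_length > 2 * frag_len, jitter_sd >= 0,
            frag_len >= 1, frag_len_sd >= 0, depth >= 1,
            occupancy_prob >= 0, occupancy_prob <= 1)
  structure(list(chrom = chrom, chrom_length = chrom_length, nrl = nrl,
                 jitter_sd = jitter_sd, frag_len = frag_len,
                 frag_len_sd = frag_len_sd, depth = depth,
                 occupancy_prob = occupancy_prob),
            class = "array_model")
}

# dyad lattice positions for a model (margins keep fragments on-chromosome)
dyad_lattice <- function(model) {
  seq.int(model$frag_len, model$chrom_length - model$frag_len, by = model$nrl)
}

# expand per-dyad fragment counts into a sorted fragment_set; positional
# jitter is per fragment (cell-to-cell heterogeneity: each fragment comes
# from a different cell's realisation of the array)
fragments_from_dyads <- function(model, dyad_pos, counts) {
  centre <- rep.int(dyad_pos, counts)
  n <- length(centre)
  if (model$jitter_sd > 0) centre <- centre + stats::rnorm(n, 0, model$jitter_sd)
  len <- pmax(1L, as.integer(round(stats::rnorm(n, model$frag_len, model$frag_len_sd))))
  start <- pmax(0L, as.integer(round(centre - len / 2)))
  end <- pmin(as.integer(model$chrom_length), start + len)
  keep <- end > start
  strand <- sample(c("+", "-"), n, replace = TRUE)
  df <- data.frame(chrom = model$chrom, start = start[keep], end = end[keep],
                   strand = strand[keep], stringsAsFactors = FALSE)
  df <- df[order(df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  fragment_set(df)
}

#' Simulate reads from a regular nucleosome array
#'
#' Dyads sit at lattice positions `i * nrl`, each retained with probability
#' `occupancy_prob`; every fragment is centred on its dyad plus
#' `Normal(0, jitter_sd)` positional noise (per fragment — each fragment
#' samples a different cell's realisation of the array); every retained dyad
#' emits `depth` fragments (or, when
#' `n_fragments` is given, exactly `n_fragments` fragments are drawn uniformly
#' over retained dyads), with fragment length `Normal(frag_len, frag_len_sd)`
#' and random strand. Deterministic under `seed`.
#'
#' @param model an [array_model()].
#' @param n_fragments optional exact total fragment count (overrides `depth`).
#' @param seed integer RNG seed.
#' @return a `fragment_set`, sorted by start.
#' @export
simulate_array_reads <- function(model, n_fragments = NULL, seed = 1L) {
  with_seed(seed, {
    dyads <- dyad_lattice(model)
    keep <- stats::runif(length(dyads)) <= model$occupancy_prob
    dyads <- dyads[keep]
    if (length(dyads) == 0L) stop("no dyads retained; raise occupancy_prob")
    counts <- if (is.null(n_fragments)) {
      rep.int(as.integer(model$depth), length(dyads))
    } else {
      tabulate(sample.int(length(dyads), n_fragments, replace = TRUE),
               nbins = length(dyads))
    }
    fragments_from_dyads(model, dyads, counts)
  })
}

#' Scenario specification for replicate / two-condition simulations
#'
#' Plants four disjoint region classes with known ground truth on the model
#' chromosome: stable regions (depth-enriched, 5% inter-replicate depth CV),
#' fuzzy regions (zero-inflated: with probability `fuzzy_dropout` a region is
#' near-absent from a replicate, otherwise sampled at reduced depth with high
#' CV), and gained/lost regions whose condition-2 depth is multiplied by
#' `fold_change` (gained) or divided by it (lost). Background dyads carry
#' moderate (`background_cv`) lognormal depth noise.
#'
#' @param chrom_length chromosome length the intervals must fit in.
#' @param stable_regions,fuzzy_regions,gained_regions,lost_regions
#'   data.frames with `start`, `end` columns (bp); defaults plant 20 stable,
#'   20 fuzzy, 10 gained and 10 lost 1-kb regions on a 10-kb cycle.
#' @param n_replicates replicates per condition, default 5.
#' @param stable_cv inter-replicate depth CV in stable (and gained/lost)
#'   regions, default 0.05.
#' @param stable_depth depth enrichment of stable/gained/lost regions,
#'   default 2.
#' @param background_cv per-dyad lognormal depth CV outside planted regions,
#'   default 0.15.
#' @param fuzzy_dropout per-replicate probability that a fuzzy region is
#'   near-absent, default 0.8.
#' @param fuzzy_base,fuzzy_floor depth multipliers of a fuzzy region when
#'   present / dropped out, defaults 0.5 and 0.02.
#' @param fuzzy_cv extra lognormal CV of a present fuzzy region, default 0.5.
#' @param fold_change occupancy fold change of gained/lost regions in
#'   condition 2, default 4.
#' @return a `scenario_spec` list; `truth` is a BED-like data.frame with one
#'   row per planted region and a `label` column.
#' @export
scenario_spec <- function(chrom_length = 2e5,
                          stable_regions = NULL, fuzzy_regions = NULL,
                          gained_regions = NULL, lost_regions = NULL,
                          n_replicates = 5L, stable_cv = 0.05,
                          stable_depth = 2, background_cv = 0.15,
                          fuzzy_dropout = 0.8, fuzzy_base = 0.5,
                          fuzzy_floor = 0.02, fuzzy_cv = 0.5,
                          fold_change = 4) {
  cycle <- 1e4
  n_cyc <- floor(chrom_length / cycle)
  base <- (seq_len(n_cyc) - 1L) * cycle
  if (is.null(stable_regions)) {
    stable_regions <- data.frame(start = base + 1000, end = base + 2000)
  }
  if (is.null(fuzzy_regions)) {
    fuzzy_regions <- data.frame(start = base + 3500, end = base + 4500)
  }
  if (is.null(gained_regions)) {
    even <- base[seq_along(base) %% 2L == 1L]
    gained_regions <- data.frame(start = even + 6000, end = even + 7000)
  }
  if (is.null(lost_regions)) {
    odd <- base[seq_along(base) %% 2L == 0L]
    lost_regions <- data.frame(start = odd + 6000, end = odd + 7000)
  }
  regions <- list(stable = stable_regions, fuzzy = fuzzy_regions,
                  gained = gained_regions, lost = lost_regions)
  for (lab in names(regions)) {
    r <- regions[[lab]]
    if (nrow(r) && (any(r$start < 0) || any(r$end > chrom_length))) {
      stop(lab, " regions fall outside the chromosome")
    }
  }
  truth <- do.call(rbind, lapply(names(regions), function(lab) {
    r <- regions[[lab]]
    if (nrow(r) == 0L) return(NULL)
    data.frame(start = r$start, end = r$end, label = lab, stringsAsFactors = FALSE)
  }))
  structure(list(chrom_length = chrom_length, regions = regions, truth = truth,
                 n_replicates = as.integer(n_replicates), stable_cv = stable_cv,
                 stable_depth = stable_depth, background_cv = background_cv,
                 fuzzy_dropout = fuzzy_dropout, fuzzy_base = fuzzy_base,
                 fuzzy_floor = fuzzy_floor, fuzzy_cv = fuzzy_cv,
                 fold_change = fold_change),
            class = "scenario_spec")
}

# region index of each dyad (0 = background), per region class
match_regions <- function(pos, regions) {
  idx <- integer(length(pos))
  for (i in seq_len(nrow(regions))) {
    idx[pos >= regions$start[i] & pos < regions$end[i]] <- i
  }
  idx
}

#' Simulate replicate fragment sets for two conditions with planted truth
#'
#' Generates `n_replicates` fragment sets per condition from the array model,
#' with per-dyad Poisson fragment counts whose expectations carry the
#' scenario's planted region effects (see [scenario_spec()]). "Gained" and
#' "lost" are oriented as condition 2 versus condition 1: a gained region has
#' `fold_change` times higher expected occupancy in condition 2.
#' Deterministic under `seed`.
#'
#' @param model an [array_model()] (its `chrom_length` must match the
#'   scenario's).
#' @param scenario a [scenario_spec()].
#' @param seed integer RNG seed.
#' @return list with `condition1`, `condition2` (lists of `fragment_set`s),
#'   `truth` (BED-like data.frame with `chrom`, `start`, `end`, `label`),
#'   `model`, `scenario`.
#' @export
simulate_replicates <- function(model, scenario, seed = 1L) {
  stopifnot(model$chrom_length == scenario$chrom_length)
  with_seed(seed, {
    lattice <- dyad_lattice(model)
    reg_idx <- lapply(scenario$regions, match_regions, pos = lattice)
    planted <- Reduce(`|`, lapply(reg_idx, `>`, 0L))
    sim_one <- function(condition) {
      lapply(seq_len(scenario$n_replicates), function(rep_i) {
        lambda <- rep(model$depth, length(lattice))
        # background: per-dyad lognormal depth noise
        lambda[!planted] <- lambda[!planted] *
          exp(stats::rnorm(sum(!planted), 0, scenario$background_cv))
        # stable-like classes: depth-enriched, one low-CV draw per region
        for (lab in c("stable", "gained", "lost")) {
          idx <- reg_idx[[lab]]
          nreg <- nrow(scenario$regions[[lab]])
          if (nreg == 0L) next
          mult <- scenario$stable_depth * exp(stats::rnorm(nreg, 0, scenario$stable_cv))
          if (condition == 2L && lab == "gained") mult <- mult * scenario$fold_change
          if (condition == 2L && lab == "lost") mult <- mult / scenario$fold_change
          lambda[idx > 0L] <- model$depth * mult[idx[idx > 0L]]
        }
        # fuzzy: zero-inflated region-level sampling
        nfuz <- nrow(scenario$regions$fuzzy)
        if (nfuz > 0L) {
          dropped <- stats::runif(nfuz) < scenario$fuzzy_dropout
          fmult <- ifelse(dropped, scenario$fuzzy_floor,
                          scenario$fuzzy_base * exp(stats::rnorm(nfuz, 0, scenario$fuzzy_cv)))
          idx <- reg_idx$fuzzy
          lambda[idx > 0L] <- model$depth * fmult[idx[idx > 0L]]
        }
        counts <- stats::rpois(length(lambda), lambda)
        fragments_from_dyads(model, lattice, counts)
      })
    }
    truth <- data.frame(chrom = model$chrom, scenario$truth, stringsAsFactors = FALSE)
    list(condition1 = sim_one(1L), condition2 = sim_one(2L),
         truth = truth, model = model, scenario = scenario)
  })
}
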