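---
title: "Methods and design notes for continuous nucleosome occupancy analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for continuous nucleosome occupancy analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

nucleotool treats nucleosome positioning data (MNase-seq and related
protocols) as a *continuous occupancy signal* rather than a set of discrete
peaks. Every mapped fragment is a genomic interval; the per-bp occupancy is
the number of fragments covering a base; windowed tracks, replicate
statistics, differential calls and repeat-length estimates are all derived
from that one primitive. The continuous view keeps low-coverage regions in
the analysis, which matters because nucleosome-depleted regions (promoters,
enhancers) are exactly the regions a peak caller discards.

### Coordinates and windows

All coordinates are BED-style 0-based half-open. A track with window size
$w$ tiles $[0, \text{span\_end})$ with windows starting at multiples of
$w$; the value of a window is

$$\langle O_R \rangle = \frac{1}{w} \sum_{p \in \text{window}} \text{cov}(p).$$

Every window, including the trailing partial one, is divided by $w$ (not by
its covered base count). This choice is deliberate: it makes the
conservation identity $\sum_j \langle O_R\rangle_j \cdot w = \sum_i
(\text{end}_i - \text{start}_i)$ exact, and it makes the windowed track the
exact block average of the per-bp coverage array, which is what the
brute-force oracle in the test suite computes. Dividing the last window by
its actual base count would inflate it whenever the chromosome span is not
a multiple of $w$.

Zero-valued windows are written by default so that window alignment across
files is positional. When zero-suppressed files are read back, absent
windows are imputed as zero — absence means "no coverage", not "missing".

### Depth normalisation

$$O_N = \frac{\langle O_R \rangle}{\text{nuc\_size} \cdot N_R / \text{chr\_length}}$$

where `nuc_size` is the mean fragment length (147 bp for mononucleosomes),
$N_R$ the number of reads, and `chr_length` the mappable span. The
denominator is the expected per-bp coverage of a uniformly distributed
library, so $O_N = 1$ means "exactly average density". `chr_length` is
operationalised as `max(end) - min(start)` of the fragments — the
data-supported span — since unmappable chromosome ends carry no fragments
and their true extent is unknowable from a BED file.

### Replicate statistics, stable and fuzzy regions

Replicate tracks are aligned positionally and summarised per window by the
mean, sample standard deviation ($n-1$ denominator) and standard error
$\mathrm{sd}/\sqrt{n}$. The *relative error* — error estimate divided by
the mean — is the stability proxy: windows with relative error $< 0.2$
(strict) and occupancy above a floor are *stable*; windows with relative
error $> 2$ (strict) are *fuzzy*; all-zero windows are skipped because
$0/0$ is undefined.

One genuine subtlety is documented rather than hidden: with the literal
definition (standard error over mean) the relative error of non-negative
data is bounded by $\sqrt{(n-1)/n} < 1$, so the conventional fuzzy cutoff
of 2 can never fire. With the coefficient of variation (SD over mean) the
bound is $\sqrt{n-1}$, which exceeds 2 from $n = 5$ replicates up.
`classify_regions()` therefore exposes `error = c("se", "sd")`: the default
`"se"` is the literal definition and is what the stable cutoff of 0.2 is
calibrated against; `"sd"` is the estimator under which the fuzzy cutoff of
2 is reachable, and is what the fuzzy-recovery tests use. We do not guess
which denominator the original field tools actually used.

### Differential occupancy

The bounded relative change

$$O_{\mathrm{diff}} = \frac{2(\langle O_{N1}\rangle - \langle O_{N2}\rangle)}
                           {\langle O_{N1}\rangle + \langle O_{N2}\rangle}
  \in [-2, 2]$$

is antisymmetric under condition swap and hits $\pm 2$ exactly when one
condition is zero. The reporting threshold (conventionally 0.99,
i.e. a ~3-fold ratio) is applied inclusively ($\ge$), a documented choice
since strictness is not specified by convention. Condition streams are
aligned positionally; windows present in only one stream count as zero in
the other; both-zero windows are skipped. Following the usual workflow,
comparisons are made on windows already classified as stable in both
conditions ("filter first"): stability filtering is the user's
responsibility and `compare_conditions()` simply compares the streams it is
given.

### Nucleosome repeat length

The phasogram counts ordered pairs of fragment starts at distances
$1 \le d \le \delta$ (each unordered pair once; zero distances excluded).
On chromatin with regular arrays it shows peaks at multiples of the repeat
length. Peaks are found on a Savitzky–Golay smoothed curve (window 51 bp,
order 3 by default — the smoother family is standard, the parameters are
ours) by local-maximum detection with three guards:

* **topographic prominence** filtering (default: 10% of the largest
  prominence) discards shallow noise bumps between the periodic peaks —
  without it, midway fluctuations survive whenever the repeat length
  exceeds twice the minimum peak separation;
* a **minimum separation** (default 100 bp) between retained peaks;
* exclusion of peaks **below 100 bp**, where duplicate and overlapping
  fragments create an artifact peak unrelated to spacing.

Peak positions are refined by parabolic interpolation on the smoothed curve
and regressed on the peak index $1, 2, \dots, k$; the slope is the NRL and
the standard error of the slope its uncertainty (undefined for two peaks).
The intercept is reported but not interpreted.

For single-end fragment length estimation the plus-strand start density is
cross-correlated with the minus-strand end density; the maximising shift is
the fragment length. In phased chromatin this function is periodic (phantom
peaks at the fragment length plus multiples of the NRL), so `max_shift`
defaults to 250 bp, below any plausible repeat length.

### Aggregate profiles and cluster maps

Feature-aligned matrices are built on a relative grid $[-\text{flank},
+\text{flank}]$ anchored at feature centres (interval features use
`floor((start+end)/2)`); minus-strand rows are reversed so $+x$ is always
downstream. Out-of-track positions are explicit gaps and all means are
gap-aware. Artifact rows — sequencing pile-ups with "suspiciously high"
occupancy — are removed when their maximum exceeds `max_fold` (default 10)
times the global median, computed once on the pre-filter matrix: the
single-pass rule is deterministic and idempotent, unlike iterative
re-filtering. The threshold is a configurable default, not a reconstruction
of any particular tool's hard-wired constant. Of the several row
normalisations historically offered by aggregate-profile tools we expose
two (none, per-row mean scaling) and document the rest as out of scope.

Row clustering uses Euclidean k-means with k-means++ initialisation under a
caller-supplied seed (Lloyd iterations, `stats::kmeans`), on raw values by
default; clusters are displayed in descending order of mean subregion
signal — a reproducible convention where the field's GUI tools leave the
order unspecified. A saved order (id, rank, cluster) can be re-applied to a
second condition's matrix by id join; we deliberately relax the stricter
"same features, same original sorting" requirement of the MATLAB-era
workflow to an id match, which subsumes it.

## The simulator: what a green test establishes

`simulate_array_reads()` emulates the fragment statistics of MNase-seq over
a phased array: dyads on a lattice with spacing `nrl` (default 190 bp, the
mammalian genome average), per-fragment Gaussian positional jitter
(default SD 20 bp, representing cell-to-cell heterogeneity — jitter is per
fragment, not per replicate, because each fragment samples a different
cell), fragment length 147 ± 3 bp, Bernoulli(0.5) strand. Fragment counts
are exact and all randomness flows from one seed.

`simulate_replicates()` plants ground truth on a 200-kb chromosome
(a deliberate scale-down from genome size to keep the default test run in
seconds; the statistics per window are depth-matched, not diluted):
per-dyad Poisson counts at base depth 20 fragments per dyad (~26 fragments
per 100-bp window, so Poisson noise does not mask the planted effects),
with

* **stable** regions: 2× depth enrichment, 5% inter-replicate depth CV —
  strongly positioned, reproducible chromatin;
* **fuzzy** regions: zero-inflated region-level sampling (dropout 0.8 per
  replicate, reduced depth when present, extra CV 0.5) — high-turnover,
  nucleosome-depleted chromatin;
* **gained/lost** regions: stable-like, with condition-2 depth multiplied
  or divided by the fold change (default 4);
* background: moderate (15% CV) lognormal per-dyad noise.

The F1 score for stable/fuzzy recovery is computed over the windows
carrying a planted truth label, because truth labels exist only for planted
intervals; background windows are intentionally unlabelled (their "true"
class is not defined by the scenario). Differential sensitivity is
region-level — a planted region counts as detected when any of its windows
is emitted — since region-edge windows are systematically fold-diluted by
fragment smearing across the boundary, a resolution property of windowed
coverage, not a defect of the statistic.

What the simulator does **not** model: sequence-dependent MNase bias, GC
bias, mappability gaps, chromosome-scale domain structure, and biological
correlation between replicates beyond shared expected depth. A green test
therefore establishes algorithmic correctness and statistical power under
idealised fragment statistics — not robustness to protocol artifacts.

## Numerical choices

* Savitzky–Golay coefficients are computed from the least-squares design in
  package (no external filter dependency); edge points are refit on
  truncated windows, preserving polynomial exactness everywhere.
* Phasogram pair counting is vectorised two-pointer enumeration, exact
  (no FFT rounding).
* Ties in `sort_rows()` break by original row order (stable sort);
  tie-breaks in k-means follow `stats::kmeans`.
* Degenerate inputs error early and loudly: empty fragment sets, single
  strands for length estimation, fewer than two replicates, fewer than two
  phasogram peaks, k exceeding usable rows.

## Known limitations

* One chromosome per track/operation; multi-chromosome analyses loop over
  `split_by_chromosome()` outputs.
* No statistical significance for differential calls — the relative-change
  statistic is a descriptive threshold, as is conventional for this
  analysis; count-based testing would need a different error model.
* `estimate_fragment_length()` assumes positioned (clustered) fragments;
  on structureless libraries the cross-correlation has no signal.
* The heatmap renderer is intentionally minimal (base graphics, clipped
  linear scale); publication graphics are expected to be drawn downstream.
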