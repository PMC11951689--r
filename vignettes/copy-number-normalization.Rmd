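---
title: "Copy-number normalization for differential chromatin analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Copy-number normalization for differential chromatin analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnaware)
```

## The model

A count-based chromatin assay measures, for a peak $i$ and sample $j$, a
fragment count whose expectation is the sum of contributions from every
DNA copy of the region:

$$
\mathbb{E}[K_{ij}] \;=\; L_j\,\bigl(\text{signal}_i + \text{background}_i\bigr)\,\frac{c_{ij}}{2},
$$

where $L_j$ is a library scale, $c_{ij}$ the regional copy number of the
sample at the peak (2 for a diploid region), and both the per-copy signal
and the in-peak background scale with $c$ — background fragments are
DNA-derived, so extra copies contribute extra background too. A
differential test that contrasts a test against a control sample
therefore sees an expected fold change of $c_\text{test}/c_\text{control}$
at every peak in a region of copy-number difference, regardless of
whether the per-copy chromatin state changed. We write
$\mathrm{CNR} = c_\text{test}/c_\text{control}$ for this regional
copy-number ratio; only the ratio matters, so no per-sample karyotype is
needed.

The correction has two stages:

1. **CNR estimation.** Coverage of both samples is summed in
   non-overlapping 50 kb bins; per-bin log2 ratios of depth-normalized
   coverage are median-centred (the modal genomic state is taken as
   CNR = 1) and segmented into runs of constant CNR. Externally produced
   segment tables (the `.cns` dialect, or BED plus a log2 column) bypass
   this stage entirely, so any dedicated copy-number caller can stand in.
2. **Count scaling.** Each peak takes the CNR of its maximal-overlap (or
   nearest same-chromosome) segment. If CNR ≥ 1 the test-condition counts
   are divided by the CNR; if CNR < 1 the control-condition counts are
   multiplied by it. The higher-copy side is always shrunk — scaling the
   lower-copy side *up* would manufacture counts and inflate the
   statistical power of the downstream test. Scaling happens after
   signal quantification but before data normalization, so size factors
   are always computed on the corrected matrix.

Running the downstream test on the raw and on the corrected matrix gives
two views of the same peak: the change in *total* signal (all copies
summed) and the change in *per-copy* signal (rescaled to a common copy
number). For a trisomic chromosome (CNR = 3/2) the pair of statuses
classifies each peak into the five dosage/compensation categories
(`classify_region()`); the four status combinations outside the five
(e.g. total down but per-copy up) are reported as `other` rather than
coerced — the algebra admits nine combinations and silently forcing them
into five would fabricate biology.

## Segmentation

`segment_log2_ratios()` uses recursive binary segmentation: within a
chromosome the candidate breakpoint maximizes the two-sample statistic
$|\bar x_L - \bar x_R| / (s\sqrt{1/n_L + 1/n_R})$, and a split is
accepted when the statistic exceeds `penalty` (default 5.0), both sides
retain at least `min_seg_bins` bins (default 5), and the mean shift is at
least `min_delta` (default 0.1 log2 units — half the smallest biologically
meaningful step, a single-copy change on a tetraploid background, is
≈ 0.32). The noise scale $s$ is estimated robustly from first differences
of the binned ratios, $s = \mathrm{MAD}(\Delta x)/\sqrt 2$ (the MAD
carrying the usual 1.4826 consistency factor), so the changepoints
themselves barely contaminate it. On a noise-free track the statistic
degenerates; a tiny floor on $s$ keeps the split ordering equal to the
ordering by standardized mean shift, which makes segmentation idempotent
on piecewise-constant input. Segment boundaries snap to bin boundaries
and invalid-bin gaps (masked regions, zero coverage) are absorbed by the
preceding segment, so every chromosome stays fully covered.

Median centring assumes the modal genomic state has CNR 1. This fails
for genome-doubling-scale events; users with such data should supply
external segments instead.

## The differential engine

The engine is a deliberately compact DESeq2-style procedure, kept
self-contained so the pipeline is testable end to end and auditable:

* **Size factors** by median-of-ratios against the per-peak geometric
  mean, computed over peaks positive in every sample.
* **Dispersions** by method of moments on normalized counts,
  $\hat\alpha = \max(10^{-8}, (s^2-\bar\mu)/\bar\mu^2)$, computed within
  each condition and pooled by degrees of freedom so group differences
  never masquerade as dispersion; a trend $\alpha(\mu) = a_1/\mu + a_0$
  fitted by robust regression; and a log-scale blend
  $\alpha = \exp\{\tfrac12\log\hat\alpha + \tfrac12\log\alpha_\text{trend}\}$.
  Before blending, the moment estimate is clamped within 3 log2 units of
  the trend: with few replicates the moment estimate's log-scale sampling
  noise spans many decades (floored values sit at $10^{-8}$), and an
  unclamped blend would drag the final dispersion toward zero and make
  the Wald statistics anticonservative.
* **Wald test**: per-peak NB group means fitted by Newton iteration on
  the log scale with size-factor offsets and fixed dispersion; the score
  equations extend continuously to the fractional counts produced by
  unrounded scaling. The statistic is log2FC over its standard error from
  the expected Fisher information, two-sided normal p-values,
  Benjamini–Hochberg adjustment across tested peaks (all-zero peaks are
  flagged untested and excluded from the family size), and the
  significance contract `padj < 0.05`.

No independent filtering, fold-change shrinkage, or outlier refitting is
applied. The engine is treated as swappable — the copy-number bias arises
in the data, not in any particular normalization, and the correction is a
pre-processing step any count-based engine can consume (rounded
half-to-even by default so integer-count engines accept the matrix; the
exact fractional matrix is retained alongside).

## Diagnostics

`bias_trend()` fits a LOESS smoother (tricube weights, local degree 1,
span 0.3) of per-peak log2 fold change on assigned log2 CNR, with an OLS
slope as the scalar summary: ≈ 1 when copy number drives the results,
≈ 0 after correction. `status_proportions()`, `cnr_binned_status()` and
`enrichment_chisq()` (a 2×3 Pearson homogeneity test, df = 2, with the
reference row replaced by reference-minus-subset when the subset is
contained in it) quantify the directional skew of calls within regions;
`ma_data()` emits the MA-plot table. Diagnostics are data tables, not
rendered figures, so they can feed any plotting layer.

## The synthetic-data generator

`simulate_experiment()` draws NB counts with mean
$L_j\,[f\,\lambda_i\,\delta_i + (1-f)\,\beta w]\,c/2$: log-normal
per-copy rates $\lambda_i$ (sdlog 1.5 — real peak intensities span orders
of magnitude) scaled so the mean peak count is `depth`; per-copy effects
$\delta_i$ for planted differential peaks or trisomy compensation
classes; and a background rate $\beta = \mathrm{depth}/\mathrm{width}$,
which makes the signal share of an average peak exactly `frip`. Bin
coverage for the CNR module is Poisson with mean proportional to
$c/2$. Default study conditions: two 10 Mb chromosomes, 50 kb bins,
2,000 non-overlapping 500 bp peaks, 3 replicates per condition, depth
100, dispersion 0.01, FRiP 0.4 — small enough to run in seconds, large
enough for stable trend and calibration estimates.

Design choices worth stating explicitly:

* **Copy-number layout.** Each euploid chromosome alternates neutral and
  altered blocks with a neutral majority (60% of the length), and altered
  blocks alternate losses and gains. Real aneuploid genomes are mostly
  neutral with roughly balanced gains and losses; an all-gain genome
  would both break the median-centring assumption of CNR estimation and
  drag median-of-ratios size factors off centre, confounding every fold
  change with a composition artifact.
* **Background scales with copy number** inside peaks, which is what
  reproduces the signal-to-noise effect: at low FRiP, weak peaks are
  lifted by background to count levels where the full CNR fold change
  becomes detectable, so copy-number false positives increase as data
  quality worsens. At dispersion much above ~0.02 the NB variance floor
  masks this mechanism, which is one reason the default dispersion is
  0.01.
* **Trisomy construction** (`make_trisomy_config()`): one designated
  chromosome uniformly at test copy 3, all others euploid; peaks on it
  receive compensation classes 80% pure dosage, 10% compensatory
  (per-copy rate × 2/3, so expected totals match the control), 5%
  over-compensatory (× 1/3) and 5% CN-independent increase (× 2). The
  classification tests run this at a high-power condition — five
  chromosomes (the trisomic one a minority of the peak set, as a real
  trisomic chromosome is), depth 2000, 6 replicates, dispersion 0.02,
  FRiP 1 and sdlog 1 — because with in-peak background a "perfectly
  compensated" peak no longer has an exactly unchanged total, so planted
  categories are only well defined on background-free signal.
* **Determinism.** All draws derive from `config$seed` through fixed
  sub-stream offsets (structure, rates, effects, library scales, counts,
  coverage), so regenerating one stage never perturbs another and equal
  seeds give bit-identical experiments.

What passing these simulations does *not* show: the generator has no GC
or mappability bias, no fragment-length structure, no peak-calling
uncertainty, and its segments are bin-aligned. Results on real data
additionally depend on the quality of the upstream coverage, exclusion
lists, and the external copy-number caller when one is used.

## Numerical and edge-case policy

* Coordinates are 0-based half-open everywhere; 1-based sources are
  converted at the file boundary. Chromosome names match exactly, with an
  explicit `strip_chr` flag instead of silent renaming.
* Scaling ratios are clipped to $[1/16, 16]$ before use so a
  near-homozygous-deletion segment cannot annihilate control counts.
* Peaks spanning a segment boundary take the maximal-overlap segment
  (ties: nearest midpoint, then leftmost) — deterministic, and faithful
  to assignment by overlap rather than averaging.
* Peaks on chromosomes without segments keep ratio 1 and are flagged
  `fallback`, never dropped; nearest-segment assignment is unbounded in
  distance but the gap is reported.
* A condition with a single replicate is refused by the dispersion
  estimator with a pointer to supplying a fixed dispersion.
* All-zero peaks report $p = p_\text{adj} = 1$, status `nd`, and are
  excluded from the BH family.

## Limitations

The pipeline corrects *between-sample* copy-number ratio; it does not
call absolute copy number, model tumour purity or subclonal mixtures, or
decompose allele-specific signal (which requires single-cell or phased
assays). Replicates of a condition share one CNR track, which matches
designs with one cell line per condition but not replicate-specific
karyotype drift. The built-in segmentation is a simple, deterministic
changepoint method adequate for arm-scale and multi-megabase events at
50 kb bins; focal events below `min_seg_bins` bins require external
segment tables from a dedicated caller.
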