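---
title: "Copy-number determination for the nebulin triplicate region by droplet digital PCR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Copy-number determination for the nebulin triplicate region by droplet digital PCR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dropletcn)
library(dplyr)
```

## The problem

The nebulin gene (*NEB*, 2q23.3) contains a ~30 kb segmental duplication in
which an eight-exon block is repeated three times per allele — the
triplicate (TRI) region.  The normal diploid copy number of the block is
therefore 6.  Gains or losses of a single block (CN 5 or 7) are benign
polymorphisms, while deviations of two or more blocks are pathogenic and
cause nemaline myopathy and related congenital myopathies.  Because the
three repeats are nearly identical, the region resists unique probe design
and is a hard target for both arrays and short-read sequencing.

Droplet digital PCR (ddPCR) sidesteps the problem: a duplexed reaction
partitions the sample into ~20,000 nanolitre droplets, amplifying the
target amplicon (FAM-labelled, shared by all three repeats) alongside a
known-diploid reference gene (*EIF2C1*/AGO1, HEX-labelled) in the same
droplets.  The fraction of negative droplets on each channel recovers the
mean occupancy per droplet by Poisson statistics, and the target:reference
rate ratio — doubled, because the reference contributes two copies per
genome — estimates the TRI copy number directly, with no external
calibration.

`dropletcn` implements the complete analysis path: amplitude import,
droplet cluster calling, Poisson quantification, run-level QC, replicate
variability, benign/pathogenic classification, method-comparison
statistics against array-CGH (aCGH), the aCGH log2 re-normalization used
to assign reference copy numbers, and a droplet simulator with known
ground truth.

## The statistical model

Let a well contain $N$ accepted droplets, with $n^-_t$ target-negative
and $n^-_r$ reference-negative droplets after thresholding.  Molecules
partition independently, so per-droplet occupancy is Poisson and

$$\hat\lambda = -\ln\left(\frac{n^-}{N}\right), \qquad
\widehat{\mathrm{Var}}(\hat\lambda) = \frac{e^{\hat\lambda} - 1}{N}$$

per channel (delta method).  The copy-number estimate is

$$\widehat{CN} = p_r \cdot \frac{\hat\lambda_t}{\hat\lambda_r}$$

with reference ploidy $p_r = 2$ by default.  The reported 95% interval is
a delta-method interval on $\log(\hat\lambda_t/\hat\lambda_r)$ with
$z = 1.96$, which keeps the bounds positive; simulation at CN 6 and
20,000 droplets puts its empirical coverage at ~95% (the acceptance
script recomputes this).  Saturated wells (no negative droplets) and
reference failures (no reference-positive droplets) are distinct error
conditions, not numbers.

Droplet volume (default 0.85 nL, the QX200 convention) enters only the
copies/µL concentration columns; the copy-number estimate is volume-free.

## Cluster calling

Each droplet falls into one of four groups — FAM±/HEX± — by comparing
its two amplitudes to per-channel cutoffs.  The boundary convention is
that an amplitude *exactly equal* to the cutoff is negative: strict
inequality for positivity, conservative toward non-detection.  Cutoffs
are intended to be set per plate, assay and channel; `auto_thresholds()`
suggests them by 1-D 2-means with deterministic initialization at the
5th/95th percentiles (reproducible without a seed), placing the cutoff
midway between the recovered centres.  A separation score — centre
distance in units of RMS within-cluster SD — below 3 flags the
suggestion unreliable, and single-cluster data (low separation with
cluster-size imbalance beyond 99.5:0.5) yields no cutoff.  Rain droplets
are handled implicitly by the threshold convention; no 2-D model-based
rain gating is attempted.

## QC filtering

Runs are removed when any single droplet cluster has 100 or fewer
accepted droplets, when the total accepted count is 10,000 or fewer
(both bounds inclusive), or when the run carries an exclusion flag
(whole-genome-amplified template, known mosaicism, other CNVs in the
gene — these are inputs assigned from orthogonal evidence, not detected
here).  Removal reasons follow a fixed priority (flags, then cluster,
then total) so reports are deterministic.  A sample survives only with
at least one passing run in each of the two assays.  No-template
controls pass with at most 2 positive droplets per channel by default;
an acceptance rule for NTCs is a configuration choice, so the budget is
a parameter and is recorded in the output.

## Replicates and per-sample values

Reproducibility (intra-assay) uses duplicates within one experiment; if
a group has more than two passing runs the two with the most droplets
form the pair.  Repeatability (inter-assay) selects, per sample and
assay, the two runs with the highest accepted droplet counts from two
separate experiments — implemented as the cross-experiment pair
maximizing first the smaller of the two totals, then their sum, with
well IDs as the final tie-break for determinism.  %CV is
$100\,s/\bar x$ with the sample ($n-1$) standard deviation everywhere;
the population denominator is available as an option since spreadsheet
conventions differ and the choice is not otherwise determined.

The per-sample copy number entering the concordance analyses defaults to
the mean of the selected inter-assay pair (falling back to the single
best run when all runs share one experiment); a "best run" rule is
available.  The aggregation rule genuinely matters for variance-style
statistics, which is one reason per-sample concordance values depend
slightly on conventions not fixed by the protocol.

## Classification

Estimates are rounded to the nearest integer with ties (x.5) rounded
away from zero — the spreadsheet ROUND convention, which at the 7.5
boundary rounds toward the pathogenic call; banker's rounding is
available.  Integer CN within ±1 of the normal CN 6 is benign; a
deviation of two or more blocks is pathogenic.  Both the normal CN and
the tolerance are parameters so the rule transfers to other segmental
duplications.  Composed, classification of a raw estimate is a step
function with breakpoints at 4.5 and 7.5.

## Concordance statistics

Method comparison against aCGH uses Pearson correlation
(`stats::cor.test`), ordinary least squares of the ddPCR estimate on the
aCGH copy number (`stats::lm`; slope reported as "estimate", with
multiple and adjusted R²), and Cohen's κ.  The κ implementation is
authored in the package: $\kappa = (p_o - p_e)/(1 - p_e)$ with the
weighted generalization (agreement weights 1 on the diagonal decaying
linearly or quadratically with category distance), the Fleiss
large-sample null SE for the p-value, and an exact-conditional Monte
Carlo alternative that resamples tables with fixed marginals
(`stats::r2dtable`).  For 2×2 tables all weightings coincide with the
unweighted statistic.  Agreement bands follow the conventional scale
(0.81–1.00 almost perfect, 0.61–0.80 substantial, 0.41–0.60 moderate,
0.21–0.40 fair, below that slight; lower edges inclusive).

Two documented subtleties:

* For the exon IV benign/pathogenic table with cells (58, 6, 20, 14)
  the standard formula gives κ = 0.352, not the 0.388 sometimes quoted
  for that assay; the value is not reproducible from those cells under
  any standard κ variant we are aware of, so the package's tests assert
  the formula value.  The exon VIII table (71, 1, 7, 19) gives 0.774,
  substantial agreement, exactly as expected.
* Multi-category (CN-level) weighted κ depends on the weighting scheme;
  since the scheme behind historically reported CN-level values is not
  determinable, the package emits linear and quadratic weightings side
  by side and asserts neither against external values.

```{r kappa}
cohen_kappa(crosstab_2x2(a = 71, b = 1, c = 7, d = 19))
cohen_kappa(crosstab_2x2(a = 58, b = 6, c = 20, d = 14))
```

## aCGH log2 re-normalization

To assign reference copy numbers from custom tiling arrays, probe log2
ratios over the *NEB* region are re-baselined locally: the mean log2 of
probes in two flanking background stretches of the gene is subtracted
from the mean log2 over the TRI region, and the result converts to a
copy number as $CN = 6 \cdot 2^{\ell}$.  Probe membership is by probe
midpoint, which is unambiguous for probes straddling a boundary.  The
published breakpoints are pairs of uncertainty intervals; the default
takes the outer edge of each pair (maximal background and TRI spans) and
an inner-edge interpretation is available behind
`acgh_regions("inner")`, since probe means are insensitive to the few
boundary probes.  One background pair is printed with descending
coordinates; both interpretations normalize it to ascending order.  A
constant baseline shift cancels exactly, and synthetic probe sets built
from a known CN round-trip to that CN to 1e-9 (asserted in tests).

## The droplet simulator

`sim_config()`/`simulate_well()` generate wells with known ground truth
under exactly the generative model the analysis assumes: independent
Poisson occupancy per channel, positivity iff ≥1 effective molecule,
Gaussian amplitude clusters, optional uniform "rain" between the
cluster means, and optional tandem-copy linkage.  Defaults, chosen once
as the study's working conditions: 20,000 droplets; reference rate
λ_ref = 0.5 copies/droplet (a mid-range working concentration for a
10 ng genomic input, and the concentration at which the Poisson
correction is exercised without approaching saturation); negative
clusters at 1000 ± 100 and positive at 8000 ± 300 amplitude units, i.e.
≥ 8 SD separation so threshold placement is unambiguous and test
failures indicate analysis defects rather than contrived overlap.

Linkage models incomplete restriction digestion of the tandem repeats:
a fraction $L$ of target copies stays joined in indivisible 3-copy
blocks that co-partition, so singles arrive at rate
$\lambda_t(1 - L)$ and blocks at $\lambda_t L / 3$, and a block turns
its droplet positive once.  At $L = 1$ and true CN 6 the six copies
partition as two allelic units, the effective target rate equals the
reference rate, and the pipeline estimate concentrates near 2.0 — a
mechanism demonstration of why complete digestion ahead of partitioning
is essential for SD copy counting, and a plausible (not established)
direction for systematic under-estimation by an assay.  The simulator
does not model PCR efficiency, competition between duplexed assays,
fluidics, or between-droplet volume variation; passing tests show the
analysis is correct under its own assumptions, not that a wet-lab assay
is accurate.

```{r linkage}
est <- sapply(1:10, function(i) {
  sim <- simulate_well(sim_config(n_droplets = 15000, true_cn = 6,
                                  linkage_fraction = 1, seed = i))
  counts <- assign_clusters(sim$droplets, thresholds(4500, 4500))
  quantify_wells(counts)$cn_estimate
})
round(mean(est), 2)
```

## Problem sizes used in tests and the acceptance script

The test suite and `scripts/acceptance.R` run the pipeline at 100 wells
per copy number over the grid {5,…,11, 14} with 15,000–20,000 droplets
per well (mean recovery within 2% of truth; classification ≥ 99%
correct), 1,000 wells for CI coverage, 50 wells for the linkage
demonstration, and a 98-sample simulated cohort whose copy-number
composition matches the published study population (22/44/12 samples at
benign CN 5/6/7; 3/5/7/2/3 at pathogenic CN 8/9/10/11/14).  These sizes
give Monte Carlo error comfortably below the asserted tolerances.  The
published per-sample data tables are not redistributable, so
cohort-level concordance values (r, slope, %CV) are checked for
coherence on the simulated cohort rather than asserted against the
published per-sample numbers.

## Known limitations

* Rain handling is purely threshold-based; heavy rain biases counts in
  a direction that depends on where the cutoff sits within the band.
* The CI is a large-sample delta-method interval; at very low positive
  counts an exact or bootstrap interval would be preferable.
* "Accepted droplets" equals all parsed droplets; vendor software may
  pre-reject droplets upstream of the export, and no re-gating is done.
* The benign/pathogenic rule assumes whole-block CNVs; partial-block
  events (none recorded to date in this region) would need different
  handling, and any pathogenic finding is intended for confirmation by
  an orthogonal method that can see beyond the TRI region.
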