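---
title: "Estimating the fetal fraction from maternal plasma SNP allele counts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating the fetal fraction from maternal plasma SNP allele counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cffmix)
```

## The problem

Cell-free DNA in the plasma of a pregnant woman is a mixture: a fraction
`f` (typically 5–20%) originates from the placenta and carries the fetal
genotype, the rest from the mother. Essentially every quantity reported
by sequencing-based noninvasive prenatal testing — aneuploidy z-scores in
particular — is interpretable only relative to `f`, so an accurate,
cheap estimate of the fetal fraction is a prerequisite for the assay.
Methods that need a male fetus (chromosome-Y coverage), parental
genotypes, or methylation markers all restrict where they can be used.
`cffmix` implements an estimator that needs nothing beyond the allele
counts of a targeted SNP panel sequenced from the plasma itself.

## The mixture model and the targeted zone

At a biallelic SNP the maternal/fetal genotype combination falls in one
of four categories, written with the maternal genotype in upper case and
the fetal in lower case: `AAaa`, `AAab`, `ABaa`, `ABab`. Let `x` and `y`
be the counts of the most and second-most frequent base at the locus
after base-quality filtering. The informative ("effective") category is
`AAab` — mother homozygous, fetus heterozygous — because there the minor
allele is carried *only* by one of the two fetal haplotypes:

* expected minor-allele dose: `f/2` of the template molecules, so
  `E[y] ≈ (f/2)·(x+y)` and the per-locus estimator is **`f = 2y/(x+y)`**;
* `ABaa` loci have minor dose `(1−f)/2`, `ABab` exactly `1/2`, and
  `AAaa` loci show minor counts only through sequencing error.

Since true genotypes are unknown, effective loci are selected
geometrically in the `(x, y)` plane. With `D` the sample depth (median
of `x+y` over all loci) and `e` the post-filter error rate, a locus is
*in the targeted zone* iff

1. `y ≤ x/3` — below the ratio line. A fetal fraction cannot plausibly
   exceed 50%, and `f = 0.5` corresponds exactly to `y = x/3`; `ABaa`
   and `ABab` loci (minor dose ≥ `(1−f)/2 > 1/4`) sit above it.
2. `y > (x+y)·e + k·sqrt(e·(x+y))` — above the error line. Error counts
   at an `AAaa` locus are Poisson with mean `(x+y)·e`; the line sits `k`
   standard deviations (`sqrt` of the mean) above that mean, `k = 3` for
   `D ≥ 100` and `k = 2` below (see *Boundary adjustments*).
3. `|x + y − D| ≤ 3·sqrt(D)` — the depth window. Per-locus coverage is
   Poisson-dispersed around `D`; loci far outside the window are
   enrichment artefacts with uninterpretable counts.

The sample estimate `f_raw` is the **median** of `2y/(x+y)` over the
zone loci — the median, not the mean, because residual contamination of
the zone (error outliers, misassigned categories, locus-specific bias)
affects the tails. All medians in the package, including `D` itself,
use the mean-of-central-pair convention for even counts, which is what
reproduces the published clinical summary statistics exactly.

Note the two distinct error rates. The zone boundary uses `e = 0.01` by
default: after discarding base calls below Phred Q20 a 1% residual error
probability is the conservative bound implied by the filter itself. The
synthetic-data generator instead uses a platform error rate
`e_sim = 0.0026` (HiSeq2000-class) to *produce* `AAaa` minor counts.
They parameterise different things — the selection rule versus the
data-generating process — and are deliberately separate arguments.

## Boundary adjustments and the depth-bias correction

Below 100-fold coverage the 3-standard-deviation error line would
swallow most of the `AAab` distribution (at `D = 65` and `f = 5%` the
expected minor count is 1.6 while the 3σ error line sits near 3.1), so
the multiplier is relaxed to `k = 2`. The relaxation, and the hard
truncation of the minor-count distribution by the error line, make the
raw median biased upward exactly where estimation is hardest: low depth
or low fraction. Empirically the raw-versus-true relation per depth is
hockey-stick shaped — identity above the detection limit, flattening
into an error floor below it (e.g. at `D = 65` the raw estimate moves
only from ≈0.087 to ≈0.115 while the truth moves from 0.03 to 0.09).

The correction is calibrated per depth on synthetic data: over a grid of
true fractions (0.5–25% in 0.5% steps, 25 replicates each) the raw
estimator is run without correction and the true-label standard
fraction is regressed on the raw estimate. Three numerical choices
matter:

* **Functional form.** The default fit is a continuous one-knot linear
  spline (`form = "hinge"`), knot chosen by residual sum of squares over
  a 25-point quantile grid. A single straight line (`form = "linear"`,
  retained for comparison) cannot follow the knee: fitted across the
  whole grid it leaves a mean absolute error of 2–3 percentage points at
  low depth, versus well under 1 point for the hinge. The hinge's right
  segment also keeps the correction near-identity where the estimator is
  unbiased, so correcting an estimate that needed no correction is
  harmless.
* **Which replicates enter the fit.** Calibration replicates whose zone
  holds fewer than `min_effective = 30` loci are excluded. Below that
  census the estimator flags its own output low-confidence, and at true
  fractions ≤ 2% a near-empty zone returns wild raw values (0.2–0.4
  against a truth of ≈0) that would act as high-leverage points and
  bend any least-squares fit. Grid cells with no usable replicate are
  dropped with a warning; a depth with fewer than 5 usable cells is an
  error.
* **Lookup.** `apply_correction` uses the calibration entry nearest in
  depth (ties toward the lower depth) rather than interpolating — a
  finite per-depth table of equations, matching how the correction is
  consumed. The corrected value is clamped to [0, 0.5].

Correction is applied when `D < 100` or `f_raw < 0.10`; above both
thresholds the raw median is already accurate and is returned as final.

## The synthetic-data generator

`simulate_dataset()` is the package's study-condition generator, used
for calibration, the evaluation sweeps, and the tests. Per dataset of
`n_loci` loci (default 10,000): the category is drawn from proportions
0.7/0.1/0.1/0.1 (`AAaa`/`AAab`/`ABaa`/`ABab`); the minor-count mean is
`e_sim·D`, `(f/2)·D`, `((1−f)/2)·D`, `D/2` respectively, the major mean
its complement to `D`; each count is drawn from a normal with variance
equal to its mean (the normal limit of Poisson-dispersed counts),
rounded, truncated at zero, and the pair is reordered so `x ≥ y`. The
`ABaa`/`ABab` means are the unique values consistent with a mother
contributing `1−f` and a fetus `f` of the template molecules. The
generator is deterministic under its seed and restores the caller's RNG
state.

The reference value for a simulated dataset ("standard f",
`standard_f_of_dataset()`) is the median of `2y/(x+y)` over loci whose
*true label* is `AAab` — it uses the labels, never the zone, so it is
independent of the boundary geometry being evaluated.

What the generator does **not** emulate: locus-specific amplification
and alignment bias, GC effects, correlated errors (strand or cycle
effects, AC/GT miscall excess), linkage between nearby panel SNPs, and
read-level artefacts — its loci are exchangeable and independent.
Passing the simulation-based checks therefore demonstrates the
estimator's statistical behaviour under the stated mixture model, not
robustness to platform-specific structure in real plasma libraries.

## What the evaluation computes

Two deviation metrics compare a deduced against a standard fraction:
`e1`, the absolute deviation in percentage points, and `e2`, the
deviation relative to the standard value. Zone selection quality is
summarised as sensitivity/specificity with `AAab` as the positive class.

* **Minimum depth** (`min_depth_sweep`): at `f = 3.5%` with 11,000
  predefined loci, 20 replicates per depth over 70–200-fold, the
  corrected estimator's mean `e1` stays below 1 percentage point at
  every depth (the acceptance script recomputes this; typical maxima
  are 0.6–0.8 points), and decreases with depth.
* **Minimum SNP count** (`min_snps_sweep`): at 65-fold the sweep reports
  both candidate readings of "enough loci": the smallest predefined
  count whose mean relative deviation drops below 1%, and the smallest
  count whose zone reliably holds more than 30 loci. At `f = 5.6%` the
  second reading evaluates to 1000–2000 predefined loci. The two
  readings do *not* coincide under this generator — see Limitations.
* **Clinical table** (`summarize_clinical_table`): the packaged 18-sample
  table reproduces, by direct arithmetic, a median low-depth deviation
  of 1.8 percentage points (range 0.6–3.6) before correction, 0.65
  (0.2–2.1) after, a median depth of 125-fold, and an overall median
  final deviation of 0.35 (0.4 at one printed decimal).

Problem sizes throughout (10,000–11,000 loci, 20–25 replicates per cell,
depth grids in steps of 5) are the package's chosen defaults: large
enough that the medians and sweep means are stable to well under the
tolerances being checked, small enough to run on a single desktop core
in minutes.

## Known limitations

* **Relative accuracy at low depth and low fraction.** At 65-fold the
  error line truncates `AAab` minor counts to `y ≥ 3`, so the raw
  median compresses below `f ≈ 9%` and the correction can only invert
  the *mean* relation, not restore per-replicate information. The mean
  relative deviation at `f = 5%` is therefore of order 10%, not the ~1%
  achievable above the detection limit; at `f = 20%` it is ≈1%. A
  >30-locus zone is consequently a necessary but not sufficient
  condition for 1% *relative* accuracy at 65-fold under this generator.
* The estimator needs a populated zone: samples whose fraction sits near
  or below the error floor (`f ≲ 2%` at typical depths) return either an
  error ("no effective SNPs") or a flagged low-confidence estimate.
* A fetal fraction above 50% is outside the geometry by construction
  (ratio line), and correction output is clamped to [0, 0.5].
* The chromosome-Y estimator (`estimate_fraction_chrY`) assumes a male
  fetus, a chrY panel free of pseudo-autosomal and X-homologous
  cross-mapping, and comparable capture efficiency between chrY and
  autosomal sites; it is an orthogonal check, not a replacement.
* Pileup-based counting performs no de-duplication; duplicate reads, if
  present, enter the counts.
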