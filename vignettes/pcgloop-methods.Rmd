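---
title: "Models and methods behind pcgloop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind pcgloop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(pcgloop)
```

`pcgloop` quantifies how Polycomb repressive complex 1 (PRC1) shapes 3D
genome architecture: multivalent long-range loops between RING1B-bound
CpG-island targets, local compaction of extended binding regions, and the
spatial clustering visible by DNA-FISH. This vignette documents the
statistical models, their assumptions, the defaults, and the numerical
conventions; the README shows the user-facing workflow.

## The observed/expected framework

All Hi-C statistics operate on balanced, binned cis contact matrices.
Because contact frequency decays steeply with genomic separation, raw
counts are not comparable across distances; every analysis therefore works
on observed/expected (O/E) values. The expected profile is computed per
chromosome as the arithmetic mean of balanced values per diagonal offset,

$$E_c(s) = \frac{\sum_{(i,j):\,j-i=s} x_{ij}}{N_c(s)},$$

where the sum and the valid-pair count \(N_c(s)\) both exclude any pair
touching an invalid (unbalanced) bin. Conventions that matter:

* **Arithmetic mean, unsmoothed, no median.** This matches the convention
  of aggregate pileup analysis. Smoothed or log-binned expected profiles
  would change O/E values slightly at large offsets where data are sparse;
  we accept that small numeric difference and document it rather than
  introduce a smoothing parameter.
* **Missing is missing.** Invalid bins propagate `NA`; they are never
  treated as zero, in either numerator or denominator. Offsets with no
  valid pair are flagged `NA`.
* **Cis only.** All analyses are within-chromosome; trans pixels are
  ignored throughout.
* O/E of a zero-count pixel is 0 wherever \(E>0\) — absence of reads is
  an observation, not missing data.

## Pileups

A point pileup averages the O/E submatrix of size \((2k+1)^2\) centred on
every eligible anchor pair. Eligibility and orientation rules:

* anchors are **region midpoint bins**; even-length midpoints round down,
  so bin assignment is deterministic;
* pairs closer than the minimum separation (default 100 kb) are excluded;
  distance strata use min-inclusive, max-exclusive intervals so that a
  stratified series partitions the unstratified pair set;
* the lower-coordinate region sits on the row axis (fixes the asymmetry
  convention);
* pixels that fall off the matrix edge or on invalid bins are excluded
  through per-pixel support counts, not zero-filled.

The default flank is 10 bins per side (a 21×21 window, ±100 kb at the
synthetic 10-kb resolution). The central pixel of the averaged matrix is
the loop-strength readout; `central_enrichment(p, k)` averages a central
k×k block when a single pixel is too noisy.

**Rescaled local pileups** quantify domain-scale compaction of
variable-length regions. Each region window (region plus
`rescale_pad = 2` region-lengths of flank per side) is bilinearly
interpolated to a fixed 75×75 grid and averaged; the result is divided by
the same procedure applied to `n_shifts = 10` randomly shifted control
windows per region. Controls shift uniformly along the chromosome,
rejecting placements whose shifted region sits closer than one region
length to the source; this makes the normalisation surface a matched
background rather than a chromosome-wide expected, which is what lets the
statistic isolate local structure. Numerical conventions: bilinear
interpolation uses pixel-centre mapping with `NA` handled by
renormalising against an interpolated validity mask; regions below the
minimum size or whose padded window leaves the chromosome are skipped and
recorded. The block summary (`block_enrichment()`) trims 25% of the
central block's width on each side, because interpolation smears the
domain boundary over roughly one source pixel and the untrimmed mean
would dilute the domain signal.

**Loopability** is the central-pixel enrichment of each region piled
against all other regions on its chromosome — a per-region measure of
loop-forming capacity. Regions with no eligible partner return `NA`
rather than a value.

## The loopability linear model

Ordinary least squares of loopability on seven standardized predictors:
ChIP read counts of H3K27me3, RING1B, MEL18, CBX2, KDM2B and RYBP over
merged peak regions, plus merged region length. Choices:

* **Population-SD standardization** (divide by \(\sqrt{n^{-1}\sum(x-\bar
  x)^2}\)), so the fit is exactly invariant under row duplication.
* Filters: regions must have positive loopability in every condition
  column supplied, and fewer than 1000 RING1B reads (very high coverage
  flags technical artifacts). Both thresholds are arguments.
* Collinearity raises a condition-number warning but still reports
  coefficients — the predictors are biologically correlated by design and
  the comparison of their relative magnitudes is the point.
* Coefficient p-values are the usual t statistics; fit quality is
  summarised by Pearson r between fitted and observed loopability.
* Chromosomes are pooled into one model.

## The ROI permutation z-score test

For a region of interest (a single interval, or an interval pair), the
observed statistic is the mean O/E over its valid pixels. The null is
built from rigid translations of the ROI along the same chromosome —
the only transformation that preserves chromosome, interval lengths,
their separation, and hence distance from the diagonal. Translations are
enumerated, filtered to exclude overlap with the original ROI, and
sampled without replacement (a short chromosome therefore reduces the
permutation count with a warning instead of silently duplicating
placements). Both the permuted means and the observed mean are log
transformed (symmetric treatment is required for the z-score to be
meaningful; a flag exposes the alternative), and

$$z = \frac{\log \bar{x}_{\mathrm{obs}} - \mathrm{mean}(\log \bar{x}_{\mathrm{perm}})}{\mathrm{sd}(\log \bar{x}_{\mathrm{perm}})}, \qquad p = 1 - \Phi(z).$$

Single-interval ROIs exclude diagonal offsets 0 and 1 from the pixel
block — the same convention as the compaction statistic — because the
first two diagonals are dominated by self-ligation-scale signal and would
dilute the domain contrast. Degenerate nulls (all permuted means equal,
as on a noise-free uniform map) return z = 0, p = 0.5. The test is
slightly conservative at the 5% level (the log transform skews the null
left); calibration on 200 null ROIs sits near 0.03.

## Compaction, compartments, insulation

**Compaction**: per genome window, the sum of O/E over intra-window
pixels excluding diagonal offsets 0 and 1 and any filtered bin, then the
group mean with a normal-approximation 95% CI (mean ± 1.96 SE; the CI
method is a convention, stated as such). Windows must be bin-aligned.
Note a resolution constraint: a domain contributes no admissible pixel
unless it spans at least 4 bins, so at 10-kb bins this statistic sees
only extended (≳40 kb) regions — the synthetic compaction analyses
therefore use extended peak regions (minimum 50 kb), the desk-scale
counterpart of analysing ≥10-kb regions in 1-kb data. For the same
divisibility reason the synthetic windows are 50 kb (5 bins) rather than
25 kb, which the 10-kb bin size does not divide.

**Compartments**: leading eigenvector of the per-chromosome Pearson
correlation matrix of O/E, invalid bins removed and re-inserted as `NA`,
sign oriented to correlate positively with GC content. Degeneracy
(leading-eigenvalue multiplicity, constant O/E, or fewer than 10 valid
bins) returns a flagged missing track rather than an arbitrary sign.

**Insulation**: per bin, the mean balanced value in the w×w diamond
crossing it (rows `(i-w)...(i-1)`, columns `(i+1)...(i+w)`), log2
normalised to the chromosome-wide mean diamond; missing within one window
of chromosome edges. The window must be a multiple of the resolution;
the synthetic-scale analyses run 1-Mb windows on 10- or 50-kb bins.
Boundary detection is resolution-limited: a 1-Mb diamond cannot resolve
the 10–100 kb domains planted at default scale, so boundary-recovery
tests use adjacent multi-Mb planted domains.

## The synthetic-data generator

The generator is first-class, tested code: it defines the conditions
under which every statistic is validated. Expected intensity at bin pair
(i, j) is a product of independent factors:

* **decay** \(f(s) = (s + s_0)^{-\alpha}\) with α = 1, s₀ = 1 bin —
  qualitatively the mammalian cis decay;
* **compartments** \(1 + c\) for same-sign bins of a planted ±1 block
  track (c = 0.3; blocks ~2 Mb in 200-kb multiples so coarse bins stay
  aligned); a correlated GC track (A-compartment ≈ +1.5% GC) supports
  eigenvector orientation;
* **CTCF loops**: factor 2.5 at convergent site-pair midpoints within a
  1.6-Mb reach, identical across conditions — this loop class is
  condition-invariant and reach-bounded by construction, which is what
  the RING1B-dependence contrast requires;
* **Polycomb loops**: factor \(1 + \lambda L_r L_q\) at peak-midpoint
  pairs, where the per-region propensity \(L_r = \exp(w^\top x_r -
  \overline{w^\top x})\) is driven by standardized log-occupancies and
  raw length with generative weights RING1B 0.6, length 0.5, CBX2 0.25,
  MEL18 0.2, RYBP −0.3, H3K27me3 −0.2, KDM2B 0 (λ = 0.4). The weights
  encode the reported structure of loop capacity — RING1B binding and
  region length dominate, canonical subunits contribute positively,
  noncanonical ones do not — so that parameter-recovery tests have a
  truth with that shape to recover. Length enters the propensity on the
  same standardized raw scale the fitted model sees.
* **domains**: factor 2 over all bin pairs inside an extended peak;
* condition profiles scale these: I53A keeps loops/domains mildly
  attenuated (0.8/0.9) with a 25% global RING1B reduction and an 80%
  reduction at a designated 20% peak subset (region-specific loss);
  KO sets Polycomb loop and domain multipliers to 0.

Counts are Poisson draws of the intensity scaled to the requested depth;
`noise_free = TRUE` returns the intensities themselves, and
`scale_to_depth = FALSE` preserves the raw factor products — together
these make planted factors exactly recoverable (the closed-form oracles
in the test suite). Occupancies are log-normal with canonical subunits
correlated to RING1B at 0.8 and noncanonical at 0.4 on the log scale.
2% of bins are masked invalid to exercise mask handling. Peaks are placed
non-overlapping on the bin grid (placement failures raise an explicit
error).

FISH nuclei place probes by a random-walk polymer law — successive
interprobe displacements are isotropic Gaussian with RMS 3D distance
0.8 µm per √Mb (ν = 0.5) — then contract Polycomb probes toward their
centroid by the condition's contraction factor (WT 0.5, I53A 0.6,
KO 1 = off), add 0.05 µm localisation noise per axis, and count foci as
single-linkage clusters at the 0.2 µm colocalization threshold. The
polymer parameters are calibration choices producing micrometre-scale
distances at megabase separations, not inferences about any particular
cell line; there is no published quantitative noise model to adopt.

**What the generator does not emulate**: balancing artifacts (weights are
unit), trans contacts, polymer dynamics, replicate structure in Hi-C,
image segmentation noise beyond Gaussian localisation error, and the
sequence composition of real CpG islands. Passing tests therefore
demonstrate that the statistics recover planted structure of the assumed
form at realistic depth — not that they are robust to every artifact of
real data.

## Formalized category definitions

The triple-probe clustering categories are defined from the count of
pairwise distances at or below the 0.35 µm threshold: 3 close pairs =
clustered (Cl), 2 = intermediate (Int), 1 = single-excluded (SE, two
probes together and one away), 0 = dispersed (Dis). The mapping from pair
counts to the named categories is this package's formalization — stated
prominently because the category names alone do not fix it.
Colocalization is strictly below 0.2 µm; the clustering threshold is
non-strict at 0.35 µm. Both thresholds are arguments.

Expression classes use the strict rule (log2 ratio ≥ 1 and BH-adjusted
p ≤ 0.01) and relaxed rule (log2 ratio ≥ 0.5); peak classification takes
unstranded TSS-to-peak-edge distances with the 0–50 kb / >100 kb rules.
The adjusted p-value is the thresholded quantity.

## Problem sizes and determinism

The default synthetic genome is 2 chromosomes × 50 Mb at 10-kb bins with
200 peaks and 5×10⁶ contacts per chromosome; parameter-recovery analyses
of the loopability model use 500 peaks. These sizes span the distance
strata of interest (up to ~50 Mb separations on one chromosome) while
keeping a full three-condition analysis on a laptop-scale budget. The
test suite validates: pileups against brute-force enumeration on toy
matrices; closed-form recovery of planted loop (factor 3, exact to 1e-9)
and domain (factor 2, within interpolation tolerance) strengths;
WT > I53A > KO ordering of Polycomb enrichment across 20 simulation
seeds; reach-bounded CTCF versus long-range Polycomb strata; ROI-test
calibration; generative-weight recovery; compartment/insulation recovery;
FISH statistics against hand enumeration; and byte-identical pipeline
reruns under a fixed seed. Every generator takes an explicit seed, child
seeds are derived deterministically, and the caller's RNG state is
restored.

## Known limitations

* No matrix balancing: inputs carry weights (synthetic maps are unit
  weighted). Real cooler files must be pre-balanced and exported to the
  text COO dialect (`bins.tsv` / `pixels.tsv` / `meta.json`).
* Insulation and compaction are resolution-limited as described above.
* The ROI test's normal tail on a log-transformed permutation null is
  mildly conservative; with 1000 permutations, p-values below ~10⁻³ are
  extrapolations of the normal approximation.
* The loopability model is linear in standardized reads; saturating or
  multiplicative occupancy effects will be absorbed into attenuated
  coefficients.
* Two-set pileups keep duplicate anchor pairs if the same pair arises
  from multiple region combinations; deduplicate regions first if that
  is not intended.
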