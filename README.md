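# pcgloop

Quantitative analysis of Polycomb (PRC1)-dependent 3D genome organisation
from binned Hi-C contact matrices and DNA-FISH measurement tables.

Canonical PRC1 — the Polycomb repressive complex built around the RING1B
ubiquitin ligase together with CBX/PHC/PCGF subunits — folds its target
loci into long-range loops and locally compacted domains. These contacts
are unusual: they connect CpG-island targets across separations up to tens
of megabases, far beyond the ~1.6 Mb reach of convergent CTCF/cohesin
loops, they survive a catalytically dead RING1B (I53A), and they collapse
when RING1B is removed. `pcgloop` implements the aggregate Hi-C and FISH
statistics with which this behaviour is measured, plus a fully synthetic
data generator with planted ground truth on which every statistic can be
validated end to end.

Everything is tidyverse-shaped: region sets, tracks and measurement tables
are tibbles, results pipe into `dplyr`, fitted objects have `tidy()` /
`glance()` methods, and result objects have `autoplot()` methods.

## What it computes

**Contact-map machinery.** A cooler-style contact matrix container
(`contact_matrix()`: bin table + upper-triangular pixel table, balancing
weights, invalid-bin mask), chromosome-wide expected profiles
E(s) = mean balanced contact at bin offset s (`compute_expected()`), the
observed/expected transform O/E(i,j) = balanced(i,j)/E(|i−j|)
(`observed_over_expected()`, `oe_matrix()`), contact-probability curves
P(s) (`contact_probability_curve()`), A/B compartment eigenvectors (leading
eigenvector of the per-chromosome O/E correlation matrix, sign-oriented by
GC content; `compartment_eigenvector()`), diamond insulation scores
(`insulation_score()`), and cross-condition profile similarity
(`profile_similarity()`).

**Pileups.** Averaged O/E submatrices over anchor pairs: distal pileups
over one or two region sets with a minimum-separation rule
(`distal_pileup()`), distance-stratified series
(`distance_stratified_pileups()`), strand-orientation classes for CTCF
sites (`oriented_pair_pileup()`), rescaled local pileups of
variable-length regions normalised to randomly shifted controls
(`rescaled_local_pileup()`), and per-region "loopability" — the
central-pixel enrichment of each region piled against all other regions on
its chromosome (`loopability_by_window()`).

**Inference.** An OLS model attributing loopability to standardized ChIP
occupancy of H3K27me3, RING1B, MEL18, CBX2, KDM2B, RYBP and merged peak
length (`fit_loopability_model()`); a permutation z-score test for
differential interaction of a region of interest, with nulls built from
rigid translations matched for chromosome and diagonal distance, log
transformation and p = 1 − Φ(z) (`roi_permutation_test()`); local
compaction (windowed O/E totals excluding the first two diagonals) versus
occupancy percentile (`compaction_by_occupancy()`); and compartment-score
change versus expression class
(`compartment_expression_association()`).

**Peak/track arithmetic.** Merging peaks separated by <5 kb
(`merge_peaks()`), read-count and RPKM quantitation
(`quantify_signal()`), occupancy and canonical/noncanonical-ratio
quartiles (`stratify_quartiles()`, `ratio_stratify()`), CGI classification
by RING1B/H3K27me3 overlap (`classify_cgis()`), genome windows and
percentile groups (`genome_windows()`, `percentile_group()`), and
expression-based peak classes using the strict (log2 ratio ≥ 1,
adjusted p ≤ 0.01, within 50 kb) and relaxed (log2 ratio ≥ 0.5, beyond
100 kb) rules (`classify_peaks_by_expression()`).

**FISH statistics.** Colocalization fractions at the 0.2 µm threshold
(`colocalization_fraction()`), Mann–Whitney comparisons
(`compare_distributions()`), the four-category triple-probe clustering
classifier at 0.35 µm — clustered / single-excluded / intermediate /
dispersed (`triple_clustering_classify()`) — and its condition×category
chi-square test (`clustering_contingency_test()`).

**Synthetic data.** `make_genome()` plants peaks with correlated
per-factor occupancies, CTCF sites, CGIs, genes and a compartment
checkerboard; `simulate_contact_map()` draws Poisson contact maps whose
expected intensity multiplies distance decay, compartments, reach-bounded
convergent-CTCF loops, occupancy-dependent Polycomb loops and domains;
`simulate_chip_tracks()`, `simulate_expression()` and `simulate_fish()`
generate the corresponding coverage, differential-expression and
interprobe-distance tables under WT / I53A / KO condition profiles
(`condition_profile()`). All generators are deterministic given a seed,
and the planted truth is returned for parameter-recovery tests.

## Worked example

```r
library(pcgloop)
cfg <- genome_config(chrom_lengths = c(chr1 = 30e6, chr2 = 30e6),
                     n_peaks = 200, seed = 7)
genome <- make_genome(cfg)
wt <- simulate_contact_map(genome, condition_profile("WT"), depth = 6e6, seed = 1)
ko <- simulate_contact_map(genome, condition_profile("KO"), depth = 6e6, seed = 2)

distal_pileup(wt, genome$peaks)
#> <hic_pileup> point | 21x21 | 10025 pair(s)/region(s) | mode=expected
#>   central enrichment: 2.042
distal_pileup(ko, genome$peaks)
#> <hic_pileup> point | 21x21 | 10025 pair(s)/region(s) | mode=expected
#>   central enrichment: 0.9625
```

Polycomb peak pairs interact twice as often as expected in WT; the
enrichment collapses to background (≈1) without RING1B. Loopability and
its occupancy model:

```r
tracks <- simulate_chip_tracks(genome, condition_profile("WT"), seed = 3)
peaks <- merge_peaks(genome$peaks)
for (f in c("RING1B", "H3K27me3", "MEL18", "CBX2", "KDM2B", "RYBP"))
  peaks <- quantify_signal(tracks[[f]], peaks, prefix = f)
peaks$enrichment1_WT <- loopability_by_window(wt, peaks)$enrichment1
fit <- fit_loopability_model(peaks, "enrichment1_WT")
tidy(fit)
#> # A tibble: 8 × 5
#>   term           estimate std.error statistic  p.value
#> 1 (Intercept)     1.80       0.0597    30.1   3.73e-69
#> 2 reads_H3K27me3 -0.197      0.0649    -3.04  2.77e- 3
#> 3 reads_RING1B    0.357      0.0986     3.61  3.98e- 4
#> 4 reads_MEL18     0.180      0.0772     2.33  2.08e- 2
#> 5 reads_CBX2      0.177      0.0811     2.19  3.02e- 2
#> 6 reads_KDM2B    -0.00748    0.0628    -0.119 9.05e- 1
#> 7 reads_RYBP     -0.227      0.0662    -3.43  7.50e- 4
#> 8 length          0.491      0.0614     8.00  1.99e-13
glance(fit)
#> # A tibble: 1 × 5
#>       r     n r.squared sigma condition_number
#> 1 0.708   174     0.501 0.788             2.76
```

RING1B occupancy and peak length carry the strongest positive
coefficients; the noncanonical subunits (RYBP, KDM2B) contribute nothing
or negatively — the fitted model recovers the planted generative weights.
A permutation test on the largest planted domain:

```r
big <- genome$peaks[which.max(genome$peaks$end - genome$peaks$start), ]
roi_permutation_test(wt, list(chrom = big$chrom, start = big$start, end = big$end),
                     n = 1000, seed = 9)
#> <roi_test> chr1:1.044e+07-1.052e+07
#>   observed mean O/E = 1.961 | z = 11.339 | p = 4.18e-30 (1000 permutations)
```

`run_polycomb_pipeline(out_dir, seed)` chains all of the above for the
three conditions and writes every table, track and summary as
TSV/BED/bedGraph/JSON with a provenance record; runs with the same seed
are byte-identical.

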