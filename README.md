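# hicvis

Chromatin is not uniformly visible to the restriction enzymes that
Hi-C-type assays rely on: condensed heterochromatin is digested less
efficiently than open chromatin, so its bins yield systematically fewer
reads and fewer contacts. Left uncorrected, this *visibility bias*
distorts both the 1D coverage of a contact map and the long-range
interaction frequencies between condensed domains. hicvis is an R
package for analysts of Hi-C, RED-seq and related digestion-based data
that (a) corrects binned 1D read counts for the confounding covariates,
(b) repurposes the remaining depletion to segment the genome into
condensed and decondensed chromatin domains, and (c) rebalances the
contact matrix itself.

## The method

**1D correction.** Read counts in fixed bins are modeled as
`x_b ~ Poisson(d * h(RE_b) * g(GC_b) * v_b)`, where `h` and `g` are
non-linear effects of restriction-site density and GC content and
`v_b <= 1` is the bin's visibility. After masking low-mappability bins
(< 0.8), counts are residualized by loess against RE density, then
against GC — in that order — and Z-scored genome-wide. What survives is
the visibility signal.

**Domain calling.** The Z-track is binarized to the sign (+1/-1); at
every bin edge the score is `mean(next 20 bins) - mean(previous 20
bins)`; a cutoff with empirical FDR < 5% is set by within-chromosome
permutation; surviving edges are thinned to directional local maxima;
inter-boundary regions with a sign proportion of at least 0.8 become
decondensed (+) or condensed (-) domains, the rest ambiguous.

**DiSCO (Distance Sorted Contact Optimization).** Contacts are split
into condensed-condensed (CC) and decondensed-decondensed (DD) lists;
for each list the mean interaction frequency `mu(s)` is computed per
genomic distance `s`; each contact keeps its residual `x - mu(s)`; the
two mean-versus-distance curves are quantile normalized; residuals are
added back: `x' = mu~(s) + (x - mu(s))`. Mixed, ambiguous and trans
contacts are untouched. A standard iterative (ICE-style) balancer,
`ice_balance()`, is included so DiSCO can be applied after matrix
balancing.

**Validation.** A seeded generator simulates genomes with known domain
segmentation, per-bin visibility, covariate tracks, counts and cis
contact matrices, so every stage is tested against ground truth. Rank
tests (exact Mann-Whitney U), Spearman correlations, overlap fractions,
per-bin state-switch tables, boundary-oriented aggregation profiles and
KO/WT log-ratio tracks cover the downstream comparisons.

## Worked example

```r
library(hicvis)

spec <- synthetic_spec(seed = 1)        # 2 x 60 Mb, 10-kb bins, delta = 0.5
truth <- generate_truth(spec)
covs <- generate_covariates(truth)
counts <- simulate_counts(truth, covs$gc, covs$re_density)

spearman_rho(track_values(counts), track_values(covs$re_density))
#> raw Spearman rho vs RE density: 0.435

corrected <- correct_visibility(counts, covs$re_density, covs$gc,
                                covs$mappability)
spearman_rho(track_values(corrected), track_values(covs$re_density))
#> corrected Spearman rho vs RE density: -0.054

domains <- call_domains(zscore_track(corrected), domain_call_params(seed = 1))
domains
#> domain_set: 159 intervals on 2 chromosome(s)
#>   ambiguous      7 intervals,     1.55 Mb
#>   condensed     76 intervals,    48.41 Mb
#>   decondensed   76 intervals,    70.04 Mb

boundary_recall(attr(domains, "boundaries"), truth$domains,
                spec$bin_size, tol_bins = 2)
#> 0.907
state_jaccard(domains, truth$domains, "condensed", spec$bin_size)
#> 0.98
```

Raw counts correlate strongly with restriction-site density (rho 0.44);
after the two loess passes the trend is gone (rho -0.05), and the
segmentation recovers 91% of the true boundaries within 2 bins with a
condensed-state Jaccard of 0.98 against the ground truth.

On a simulated contact matrix (two 20-Mb chromosomes), DiSCO flattens
the distance-stratified imbalance between decondensed and condensed
interactions:

```r
mspec <- synthetic_spec(chrom_lengths = c(20e6, 20e6), seed = 1)
mtruth <- generate_truth(mspec)
cm <- simulate_matrix(mtruth)
median(ratio_curve(cm, mtruth$domains)$ratio)
#> median DD/CC ratio before DiSCO: 4.04
median(ratio_curve(disco_correct(cm, mtruth$domains), mtruth$domains)$ratio)
#> median DD/CC ratio after DiSCO:  1.03
```

A DD/CC ratio of 4 is what visibility 0.5 predicts (contacts scale with
`v_i * v_j = 0.25`); after DiSCO the two classes match (ratio ~1).

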