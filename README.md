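# dielarray

Diel gene expression analysis for targeted microarray metatranscriptomes
of marine microbial populations — built around the kind of study that
samples an uncultivated organism such as the N₂-fixing cyanobacterial
symbiont UCYN-A over a full light–dark cycle (8–10 time points at 3 h
intervals, duplicate samples) with a probe-based expression array, and
asks which genes are detected, which are expressed with 24 h
periodicity, when they peak, and how that changes between habitats.

The package is written tidyverse-style: user-facing functions take a
data frame first and return tibbles, fitted objects have broom-style
`tidy()`/`glance()` methods, and result types have `autoplot()`/`plot_*()`
functions.

## What it computes

**Platform QC.** Probe screening against reference sequences of the
other sublineages (local alignment, hit at ≥ 95% identity over ≥ 95% of
the probe, both strands, gaps as mismatches, `N` matches nothing), greedy
CD-HIT-style probe clustering with rejection of clusters spanning
sublineages or genes (whitelist for conserved genes such as *nifH*), and
probe-set coverage summaries.

**Normalization.** Quantile normalization across samples (ties share the
mean reference value) followed by Tukey median-polish summarization of
each gene's log2 probe × sample block; the gene level in sample *s* is
overall + column effect.

**Detection.** Per sample, a noise floor (μ, σ) from the bottom decile
of gene levels; a gene needs SNR = (level − μ)/σ strictly above 5 in at
least one sample, *and* to beat the least concentrated external spike-in
control in strictly more than 3 samples, by raw intensity or by predicted
transcript count from an OLS calibration of log2 count on log2 intensity
across the spike ladder.

**Diel calling.** For each detected gene, a Fourier score at period 24 h
on the standardized, replicate-averaged series,

    F = sqrt( (Σᵢ xᵢ cos ωtᵢ)² + (Σᵢ xᵢ sin ωtᵢ)² ),  ω = 2π/24 h,

with significance from per-gene AR1 background simulations: the FDR at
score F is min(1, mean_b #{background ≥ F} / #{observed ≥ F}), made
monotone in F; genes with FDR < 0.25 are diel. Diel profiles are
clustered (1 − Pearson distance, centroid linkage) with bootstrap
support over resampled time points; peak/trough times are
replicate-and-day-averaged arg-max labels on the sunrise-anchored
`L3…L12/D3…D12/2L3…` clock.

**Cross-habitat statistics.** Detection overlap, median within-sample
z-scores for cross-site scatter, Welch and one-tailed paired/unpaired t
tests, Fisher's exact test of diel status by habitat, Spearman/Pearson
and per-pathway cross-site correlations, a pathway × source quantile
matrix on a 5% grid (monotone-invariant, so array intensities and
sequencing counts can share one heat map), and circular peak-shift
tables (maintained / < 6 h / ≥ 6 h).

**Environment.** Mixed-layer depth as the interpolated crossing of
σθ(10 dbar) + 0.03 kg m⁻³; 2-D NMDS of transcript profiles (Kruskal
stress, Euclidean distances); environmental vectors fitted to the
ordination with 999-permutation p-values; per-gene correlations to CTD
variables with group medians.

**Synthetic data.** A first-class generator plants ground truth — diel
status and phase, AR1 noise, probe affinities, a spike-in ladder whose
least concentrated member bounds detection, sinusoidal CTD covariates,
and a density profile with a known mixed-layer depth — so every stage is
testable offline.

## Worked example

```r
library(dielarray)

cfg <- default_config(seed = 1L)
cfg$genes$n_genes <- 80L
cfg$diel$B <- 100L
cfg$timepoint_subset <- c("L3", "L6", "L9", "L12", "D3", "D6", "D9",
                          "2D12")
run <- run_pipeline(cfg)
run$summary
#> # A tibble: 10 × 2
#>    quantity               value
#>    <chr>                  <dbl>
#>  1 n_genes             8   e+ 1
#>  2 site_a_detected     6.8 e+ 1
#>  3 site_a_diel         9   e+ 0
#>  4 site_b_detected     6.8 e+ 1
#>  5 site_b_diel         6.8 e+ 1
#>  6 cross_site_detected 5.6 e+ 1
#>  7 fisher_p            2.27e-23
#>  8 frac_shift_ge6      6.25e- 1
#>  9 site_a_diel_subset  1   e+ 1
#> 10 mld                 2.8 e+ 1
```

Reading the summary: of 80 simulated genes, 68 pass detection at the
open-ocean-style site (`site_a`; the 12 missing ones are the planted
low-baseline genes below the spike-in floor), and 9 are called diel
there versus 68 at the diel-rich coastal-style site (`site_b`) — so the
Fisher test on the diel-by-habitat table over the 56 cross-site detected
genes is extreme (p ≈ 2 × 10⁻²³), and 62.5% of cross-site genes shift
their peak time by 6 h or more. Rerunning the diel scan on the 8 shared
time points (`site_a_diel_subset`) changes the open-ocean count only
slightly, and the mixed-layer depth recovered from the synthetic density
profile is the planted 28 dbar.

Individual stages are plain functions on tibbles, e.g.

```r
d   <- make_design(10, 3, n_replicates = 2, sunrise_hour = 6, daylight = 12)
tr  <- make_gene_truth(200, prop_diel = 0.2, seed = 1)
e   <- simulate_expression(d, tr, noise_sd = 0.5, seed = 2)
scan <- fdr_fourier(e, d, B = 200, seed = 3)
glance(scan)
autoplot(scan)
peak_times(e, d)
```

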