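# poolgsi

Selecting population-informative SNPs from pooled-DNA allele frequencies,
and measuring how many markers genetic stock identification (GSI) needs.

## The problem

Managing mixed-stock fisheries (and many other conservation settings)
requires assigning individuals of unknown origin back to their population
of origin from genetic markers. Genotyping thousands of SNPs in every
candidate baseline population is expensive; hybridising *pooled* DNA to a
SNP array and reading population allele frequencies directly
("allelotyping") is not. poolgsi implements that full analysis chain for
biallelic SNP panels:

1. **Allelotyping** — convert pooled-array theta values to B-allele
   frequencies by piecewise-linear interpolation between per-locus
   genotype-cluster means (`theta_to_frequency()`), with replicate quality
   control (`filter_replicate_quality()`, replicate SD ≤ 0.02 by default)
   and replicate averaging (`pool_frequencies()`).
2. **Population summaries** — expected heterozygosity `2p(1−p)`,
   Weir–Cockerham-type global and pairwise F\_ST from frequencies, Delta
   (mean absolute pairwise frequency differential), Nei's D\_A distance
   `1 − mean_l Σ_a √(p_i p_j)`, and neighbor-joining trees with
   locus-bootstrap support.
3. **Marker selection** — rank loci by global F\_ST, pairwise F\_ST, Delta,
   or a Bayesian F-model outlier scan (`scan_outliers()`, a reversible-jump
   MCMC giving per-locus posterior odds of selection and q-values; selected
   = log10 PO > 1 and q < 0.05), classify the upper quartile, prune linked
   loci (> 1 cM), and build top-K or random panels.
4. **GSI engine** — simulate baseline (100/population) and mixture
   (500/population) genotypes under HWE/LE, compute Rannala–Mountain
   genotype likelihoods, estimate stock composition by EM, assign every
   individual, and fit the marker-requirement model `y = exp(a + b/x)` to
   accuracy-vs-panel-size curves to solve for the panels needed for 80, 90
   and 95 % correct assignment.

A synthetic-data module (Balding–Nichols frequencies with planted outlier
loci, jittered cluster references, noisy pool replicates, Dirichlet
STR-like loci) generates every input with known truth, so the whole
pipeline is testable offline.

## Worked example

```r
library(poolgsi)

# a synthetic study: 12 weakly diverged populations, 800 SNPs, 4 replicates
sim  <- generate_population_frequencies(n_pops = 12, n_loci = 800,
                                        fst = 0.025, seed = 1)
ref  <- generate_cluster_reference(800, jitter_sd = 0.02, seed = 2)
reps <- generate_pool_replicates(sim$freqs, ref, n_replicates = 4,
                                 theta_noise_sd = 0.01, seed = 3)

qc <- filter_replicate_quality(reps, max_sd = 0.02)
qc
#> Replicate QC (max SD 0.02): 745 / 800 loci retained (55 dropped)
freqs <- pool_frequencies(reps, ref, qc = qc)

# rank by mean pairwise F_ST, prune linked loci, measure assignment power
div <- locus_divergence(freqs, n_ind = 50)
rk  <- prune_linked(rank_loci(div, method = "pairwise_fst"),
                    generate_panel_map(800, 20, 100, seed = 4), min_cM = 1)
cv  <- accuracy_curve(freqs, rk, sizes = c(25, 50, 100, 200, 300),
                      n_baseline = 100, n_mixture = 200, seed = 5)
dplyr::select(cv, size, independent_alleles, overall_pct)
#>    size independent_alleles overall_pct
#> 1    25                  25        48.5
#> 2    50                  50        69.6
#> 3   100                 100        87
#> 4   200                 200        96.8
#> 5   300                 300        99.0

fit_required_markers(cv)
#> Exponential marker-requirement fit: y = exp(4.6606 -19.74 / x); asymptote 105.7%
#> # A tibble: 3 × 3
#>   target_pct required_markers attainable
#>        <dbl>            <dbl> <lgl>
#> 1         80               71 TRUE
#> 2         90              123 TRUE
#> 3         95              185 TRUE
```

Read the numbers as: with panels of the 25–300 best pairwise-F\_ST SNPs,
overall correct assignment of a simulated mixed sample rises from 48.5 % to
99.0 %; the fitted exponential says 71 of these SNPs reach 80 % accuracy,
123 reach 90 %, and 185 reach 95 % for this level of differentiation.
`autoplot(cv, fit)` draws the curve; `scan_outliers()`, `nei_da()`,
`bootstrap_consensus()` and `gsi_pipeline()` cover the remaining stages,
and `tidy()`/`glance()` methods give tabular summaries of fitted objects.

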