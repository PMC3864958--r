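---
title: "Methods: pooled-DNA allelotyping, informative-SNP selection and GSI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pooled-DNA allelotyping, informative-SNP selection and GSI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

poolgsi implements a complete analysis chain for a common design in
conservation genetics: population allele frequencies are estimated cheaply
from *pooled* DNA hybridised to a SNP array, the most population-informative
markers are ranked and pruned, and the power of marker panels for genetic
stock identification (GSI) — assigning individuals of unknown origin in a
mixed sample back to baseline populations — is quantified by simulation.
This vignette explains the models behind each stage, the tunable parameters
and their defaults, and the design decisions taken where the methodology
left genuine choices.

## Allelotyping: from array theta to allele frequency

A two-colour SNP array summarises the two allelic signals of a sample as a
normalised *theta* in [0, 1]. For an individual, theta clusters near three
values (AA, AB, BB genotypes); for a DNA pool it moves continuously with the
pool's B-allele frequency. Because the cluster positions differ by locus,
`theta_to_frequency()` interpolates the pool's theta piecewise-linearly
between the per-locus mean cluster thetas estimated from individually
genotyped reference samples: theta at the AA cluster maps to frequency 0, at
the AB cluster to 0.5, at the BB cluster to 1, clamped outside. The map is
monotone and exactly invertible, which the synthetic generator exploits (the
zero-noise round trip is an identity to machine precision, a property the
tests assert).

Technical replicates of each pool guard against hybridisation noise.
`filter_replicate_quality()` interprets "variation of theta among
replicates" as the sample standard deviation (the conventional replicate-QC
statistic, and the quantity our noise model controls); a locus is dropped
*panel-wide* when any population's replicate SD exceeds `max_sd` (default
0.02), because downstream statistics need a complete frequency matrix. A
single replicate yields SD 0 with a warning — one measurement cannot show
irreproducibility. `pool_frequencies()` converts each replicate's theta
first and then averages frequencies; averaging thetas before conversion
differs only at second order (the correction is piecewise linear), but
converting first keeps every replicate on the scale the statistics use, so
that order is fixed as the contract.

## Population summaries

Expected heterozygosity is `2p(1-p)` per biallelic locus (`1 - sum(p^2)`
multiallelic), averaged over loci per population. Differentiation uses the
Weir–Cockerham variance-components framework on the frequency matrix with
`2 * n_ind` gene copies per pool (default `n_ind = 50`). One deliberate
departure from the classic estimator: the classic form subtracts the
within-population mean square from the among-population mean square to
remove *binomial genotype-sampling* variance. Pool frequencies are not
sample frequencies of that kind — their error is technical and already
handled by replicate QC — so subtracting the sampling term biases the
estimate down by roughly `(1-F)/(2n)` when frequencies measure the
population directly. The default (`sampling_correction = FALSE`) therefore
keeps the variance decomposition but omits the numerator subtraction, which
is unbiased for the divergence parameter of the generating F-model;
`sampling_correction = TRUE` restores the classic behaviour for
genotype-derived frequencies. Negative per-locus values are retained in
averages (truncating would bias them); loci monomorphic in every population
have no defined estimate and are `NA`, excluded from summaries and ranked
last.

`delta_differential()` computes the mean absolute pairwise frequency
difference per locus, and `nei_da()` the allele-sharing distance
`1 - mean_l sum_a sqrt(p_i p_j)` with both alleles of a biallelic locus
contributing. Trees are Saitou–Nei neighbor joining (via ape) with negative
branches truncated to zero; `bootstrap_consensus()` resamples loci with
replacement, rebuilds the tree per replicate, and reports the majority-rule
consensus with percent split support, matching the field's convention of
flagging splits under 80%.

## Ranking markers and the outlier scan

`rank_loci()` sorts descending by global F_ST, mean pairwise F_ST, Delta, or
outlier posterior odds, with ties broken by locus id so rankings are
deterministic. The pairwise-F_ST locus score is the mean over population
pairs, consistent with how Delta is aggregated. `classify_upper_quartile()`
flags loci at or above the 75th percentile (type-7 linear-interpolation
quantile). `prune_linked()` scans the ranking greedily, keeping a locus only
if it is more than `min_cM` (default 1 cM) from every kept locus on the same
chromosome; loci missing from the map are treated as unlinked, with a
warning, so a patchy map never silently shortens a panel. Random control
panels are drawn without pruning — pruning is part of the ranked-panel
recipe only.

The outlier scan re-implements the Bayesian F-model: the B-allele count of
population *j* at locus *l* is beta-binomial with mean equal to the locus's
ancestral frequency and a concentration whose logit-F_ST decomposes as
`alpha_l + beta_j` — a locus-specific selection effect plus a
population-specific drift effect. A reversible-jump MCMC (Rcpp) switches
each `alpha_l` in and out of the model; the posterior inclusion probability
yields posterior odds of selection, and the q-value of a locus is the mean
posterior exclusion probability among loci with at least its odds. Priors
follow the scan's conventions: `alpha ~ N(0, 1)`, `beta ~ N(-1, 1.8)`,
uniform ancestral frequencies, prior odds 10 for neutrality. Pool
frequencies are converted to pseudo-counts `round(2 n p)` of `2 n` gene
copies — an approximation (the pool estimate is treated as an exact count)
that is conservative for calibration because it understates no variance
component at the nominal pool size.

Numerical choices: proposals for frequencies (logit scale), `alpha` and
`beta` are random walks adapted toward ~35% acceptance during burn-in; the
jump proposal for `alpha` is a per-locus normal tuned by a pilot phase run
with all locus effects included; the combined logit F_ST is clamped to
±15 to keep the beta-binomial finite. Default chain sizes are pilot 3000,
burn-in 4000, and 2500 retained samples at thinning 2 (~12,500 sweeps).
These are smaller than the week-scale settings a standalone scan program
might default to; with pilot-tuned proposals the chain mixes well at the
panel sizes this package targets (the test suite verifies calibration —
essentially no flagged loci on neutral 20-population × 1000-locus panels —
and >70% recall of planted outliers at divergence multiplier 8), and all
settings remain adjustable through the `mcmc` argument. Posterior inclusion
probabilities are clamped away from 0 and 1 by half a Monte-Carlo unit so
posterior odds stay finite.

## GSI: simulated baselines, Rannala–Mountain assignment, EM mixtures

GSI methods need genotypes, not frequencies, so `simulate_genotypes()`
draws individuals as Binomial(2, p) per locus under Hardy–Weinberg and
linkage equilibrium — the same simplification the study design makes. The
two-stage design is preserved: a baseline of (by default) 100 genotypes per
population is simulated and reduced to allele counts, and a *disjoint*
mixture of 500 per population is assigned against it. No leave-one-out is
applied; since baseline and mixture are independent draws this mainly
inflates accuracy through optimistic baselines, a caveat inherited from the
design itself.

Assignment likelihoods use the Rannala–Mountain posterior-predictive
genotype frequencies: with baseline counts `(x_A, x_B)` of `n` gene copies
and a Dirichlet(1/2, 1/2) prior, `P(AA) = (x_A+1/2)(x_A+3/2)/((n+1)(n+2))`,
`P(AB) = 2(x_A+1/2)(x_B+1/2)/((n+1)(n+2))`, analogously `P(BB)` — never
zero, so a private allele penalises rather than annihilates a likelihood.
`em_mixture()` maximises the mixture likelihood over stock proportions by
EM (E-step memberships, M-step their means), stopping when the monotone
log-likelihood changes by less than `tol = 1e-6` (this package's choice;
the reference mixed-stock software does not document its criterion).
`gsi_assign()` assigns every individual to its maximum-posterior stock with
the EM proportions as prior by default (`prior = "uniform"` gives the plain
assignment-test behaviour); ties break by population order with a warning.

`accuracy_curve()` repeats simulate–assign over a grid of panel sizes
(default 25–300, the conventional grid) and records percent-correct against
the panel's independent-allele count `sum(k_l - 1)` — the axis on which SNP
and microsatellite panels are comparable. `fit_required_markers()` fits
`y = exp(a + b/x)` by least squares on `log y` against `1/x`
(deterministic, and the model linearises exactly), then inverts to
`required_x(t) = ceiling(b / (log t - a))`, defined only when the target
lies below the asymptote `exp(a)`; a flat fitted curve reports attained
targets at the smallest observed panel. Whether such a regression should be
fitted to pooled overall accuracy or averaged per-population curves is
ambiguous in the field; overall accuracy is used here.

## The synthetic-data generator

The generator exists so that every stage is testable, with known truth, at
desk scale. Population frequencies follow the Balding–Nichols F-model
(Beta with mean equal to the ancestral frequency and variance
`p(1-p) F`) — the standard generative counterpart of F_ST-based analyses;
monomorphic draws are retained, as real marginal frequency spectra include
them. Outlier loci are planted by multiplying F at a flagged fraction of
loci (effective F capped below 1), which is exactly the signal the F-model
scan is built to detect. Cluster references jitter the (0.05, 0.5, 0.95)
centres with Gaussian noise (SD 0.02), redrawing the rare locus that loses
strict ordering. Pool replicates add truncated Gaussian noise to the exact
inverse of the theta correction; the noise law of real replicate thetas is
not documented by array vendors, so Gaussian truncation is an assumption
chosen to match the SD-based QC statistic, not a claim about the
instrument. Multiallelic (STR-like) loci use the Dirichlet analogue of
Balding–Nichols with concentration `(1-F)/F`.

What the generator does *not* emulate: raw two-channel intensities,
within-population linkage disequilibrium, null alleles, or genotyping
error in the baseline reference — so passing tests demonstrate the
statistical machinery, not robustness to those artefacts of real data.

Default test scale is about 20 populations × 1000 loci × 4 replicates,
which keeps the full suite in minutes; the study-scale script
(`scripts/acceptance.R`) runs 23 populations × 2880 loci with a two-tier
divergence structure — eighteen weakly diverged populations
(F ~ U(0.01, 0.06)) and five strongly diverged ones (F ~ U(0.15, 0.30)) —
chosen once to mirror a coastal-rivers-plus-landlocked system in which
pairwise F_ST spans roughly 0.01–0.3 and per-population heterozygosity
0.23–0.35, with 5% of loci planted as outliers at divergence multiplier 3.

## Known limitations

* Pseudo-counts feed the outlier scan; very small pools would make the
  rounding coarse.
* The F-model scan assumes a shared ancestral pool (star phylogeny);
  strong hierarchical structure can inflate apparent locus effects, as for
  any scan of this family.
* Frequency-based F_ST needs nominal pool sizes; these enter as weights
  and (optionally) sampling corrections, and results at very unequal pool
  sizes depend on them.
* Accuracy curves share one baseline/mixture simulation per panel size;
  replication across seeds is the caller's loop if uncertainty bands are
  needed.
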