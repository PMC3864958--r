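# Bayesian F-model outlier scan: posterior odds of a locus-specific
# selection effect, with q-values for Bayesian FDR control.

#' Scan loci for outlier differentiation under the Bayesian F-model
#'
#' Re-implements the Foll-Gaggiotti F-model scan: allele counts follow a
#' beta-binomial whose locus-by-population F_ST decomposes on the logit
#' scale into a locus (selection) effect `alpha` and a population (drift)
#' effect `beta`; a reversible-jump MCMC switches each locus's `alpha` in
#' and out of the model. The posterior inclusion probability gives posterior
#' odds `PO = pi / (1 - pi)` of the selection model; `log10(PO) > 1` is
#' conventionally read as strong evidence and `> 2` as decisive. The
#' q-value of a locus is the mean posterior exclusion probability among loci
#' with at least its posterior odds.
#'
#' Pool frequencies carry no individual genotypes, so counts are formed as
#' `round(2 * n_ind * p)` B alleles out of `2 * n_ind` gene copies per
#' population — an approximation that treats the pool estimate as an exact
#' allele count.
#'
#' @inheritParams fst_global
#' @param prior_odds Prior odds of the neutral over the selection model
#'   (default 10, the scan's conventional default).
#' @param mcmc Named list overriding any of `pilot`, `burn_in`, `n_samples`,
#'   `thin` (defaults 3000, 4000, 2500, 2).
#' @param seed Integer seed; the chain is deterministic given the seed.
#'
#' @return A tibble of class `outlier_scan` with columns `locus`,
#'   `log10_po`, `q_value`, `alpha`, `fst`, `selected`
#'   (`log10_po > 1 & q_value < 0.05`), plus attribute `mcmc` recording the
#'   settings used. Posterior inclusion probabilities are clamped away from
#'   0 and 1 by half a Monte-Carlo unit so posterior odds stay finite.
#' @export
scan_outliers <- function(freqs, n_ind = 50, prior_odds = 10,
                          mcmc = list(), seed = 1L) {
  p <- freq_matrix(freqs)
  if (ncol(p) < 2) abort("outlier scan requires >= 2 populations")
  if (prior_odds <= 0) abort("`prior_odds` must be > 0")
  set <- utils::modifyList(
    list(pilot = 3000L, burn_in = 4000L, n_samples = 2500L, thin = 2L),
    mcmc)
  n_copies <- gene_copies(n_ind, colnames(p))
  counts <- round(sweep(p, 2, n_copies, `*`))
  totals <- matrix(rep(n_copies, each = nrow(p)), nrow(p), ncol(p))
  fit <- with_seed(seed, {
    .outlier_mcmc(counts, totals, prior_odds,
                  as.integer(set$pilot), as.integer(set$burn_in),
                  as.integer(set$n_samples), as.integer(set$thin))
  })
  S <- fit$n_samples
  pi_incl <- pmin(pmax(fit$incl_prob, 0.5 / S), 1 - 0.5 / S)
  out <- tibble::tibble(
    locus = rownames(p),
    log10_po = log10_posterior_odds(pi_incl),
    q_value = bayes_q_values(pi_incl),
    alpha = fit$alpha,
    fst = fit$fst
  )
  out$selected <- out$log10_po > 1 & out$q_value < 0.05
  class(out) <- c("outlier_scan", class(out))
  attr(out, "mcmc") <- set
  attr(out, "beta") <- setNames(fit$beta, colnames(p))
  out
}

# log10 posterior odds of the selection model from its posterior
# probability; > 1 reads as strong evidence, > 2 as decisive.
log10_posterior_odds <- function(pi_incl) {
  log10(pi_incl / (1 - pi_incl))
}

# Bayesian FDR q-values: for each locus, the mean posterior probability of
# neutrality among loci with inclusion probability at least as high.
bayes_q_values <- function(pi_incl) {
  ord <- order(pi_incl, decreasing = TRUE)
  q_sorted <- cummean(1 - pi_incl[ord])
  # enforce monotonicity in the ordering (running mean already is
  # non-decreasing, but ties in pi must share a q-value)
  q <- numeric(length(pi_incl))
  q[ord] <- q_sorted
  # loci with identical posterior odds share the largest q among them
  split_q <- split(seq_along(pi_incl), pi_incl)
  for (idx in split_q) q[idx] <- max(q[idx])
  q
}

cummean <- function(x) cumsum(x) / seq_along(x)

#' @export
print.outlier_scan <- function(x, ...) {
  cat(sprintf(
    "F-model outlier scan: %d loci, %d selected (log10 PO > 1 & q < 0.05)\n",
    nrow(x), sum(x$selected)))
  NextMethod()
}
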