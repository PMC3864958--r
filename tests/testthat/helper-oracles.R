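# Independent brute-force oracles and fixture builders shared across tests.
# Each oracle is written as a direct enumeration of the defining formula,
# kept deliberately separate from the package's vectorised implementations.

# random wide frequency table
random_freq_table <- function(n_pops, n_loci, seed) {
  withr_seed <- function(expr) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    expr
  }
  withr_seed({
    m <- matrix(runif(n_pops * n_loci), n_loci, n_pops,
                dimnames = list(sprintf("L%04d", seq_len(n_loci)),
                                sprintf("pop%02d", seq_len(n_pops))))
    tibble::as_tibble(m, rownames = "locus")
  })
}

# Delta: explicit loop over unordered pairs
oracle_delta <- function(freqs) {
  m <- as.matrix(freqs[-1])
  pops <- seq_len(ncol(m))
  vapply(seq_len(nrow(m)), function(l) {
    acc <- 0; np <- 0
    for (i in pops) for (j in pops) if (i < j) {
      acc <- acc + abs(m[l, i] - m[l, j]); np <- np + 1
    }
    acc / np
  }, numeric(1))
}

# per-locus Weir-Cockerham theta for one set of populations, scalar loop form
oracle_wc_locus <- function(p, n_copies, sampling_correction = FALSE) {
  r <- length(p)
  N <- sum(n_copies)
  n_c <- (N - sum(n_copies^2) / N) / (r - 1)
  pbar <- sum(n_copies * p) / N
  msp <- sum(n_copies * (p - pbar)^2) / (r - 1)
  msg <- sum(n_copies * p * (1 - p)) / (N - r)
  num <- if (sampling_correction) msp - msg else msp
  den <- msp + (n_c - 1) * msg
  if (den > 0) num / den else NA_real_
}

# per-locus mean pairwise F_ST by explicit pair loop
oracle_pairwise_mean <- function(freqs, n_ind = 50) {
  m <- as.matrix(freqs[-1])
  n <- rep(2 * n_ind, 2)
  vapply(seq_len(nrow(m)), function(l) {
    vals <- c()
    for (i in seq_len(ncol(m))) for (j in seq_len(ncol(m))) if (i < j) {
      vals <- c(vals, oracle_wc_locus(c(m[l, i], m[l, j]), n))
    }
    mean(vals, na.rm = TRUE)
  }, numeric(1))
}

# Nei D_A by explicit double loop over loci and both alleles
oracle_nei_da <- function(freqs) {
  m <- as.matrix(freqs[-1])
  k <- ncol(m)
  d <- matrix(0, k, k, dimnames = list(colnames(m), colnames(m)))
  for (i in seq_len(k)) for (j in seq_len(k)) if (i != j) {
    share <- 0
    for (l in seq_len(nrow(m))) {
      share <- share + sqrt(m[l, i] * m[l, j]) +
        sqrt((1 - m[l, i]) * (1 - m[l, j]))
    }
    d[i, j] <- 1 - share / nrow(m)
  }
  d
}

# Rannala-Mountain genotype probability: marginal beta-binomial derivation,
# integrating Binomial(2, p) against the Beta(x_B + 1/2, x_A + 1/2)
# posterior in closed form.
oracle_rm_prob <- function(g, x_b, n) {
  x_a <- n - x_b
  choose(2, g) * beta(x_b + 0.5 + g, x_a + 0.5 + (2 - g)) /
    beta(x_b + 0.5, x_a + 0.5)
}

# Two hierarchical clusters of populations: deep split at fst_between,
# shallow divergence fst_within inside each cluster.
two_cluster_freqs <- function(n_per_cluster = 3, n_loci = 300,
                              fst_between = 0.2, fst_within = 0.02,
                              seed = 1) {
  anc <- generate_population_frequencies(2, n_loci, fst = fst_between,
                                         seed = seed)
  m <- as.matrix(anc$freqs[-1])
  clamp <- function(x) pmin(pmax(x, 0.01), 0.99)
  fA <- generate_population_frequencies(n_per_cluster, n_loci,
                                        fst = fst_within,
                                        ancestral = clamp(m[, 1]),
                                        seed = seed + 1)$freqs
  fB <- generate_population_frequencies(n_per_cluster, n_loci,
                                        fst = fst_within,
                                        ancestral = clamp(m[, 2]),
                                        seed = seed + 2)$freqs
  names(fA)[-1] <- paste0("A", seq_len(n_per_cluster))
  names(fB)[-1] <- paste0("B", seq_len(n_per_cluster))
  dplyr::bind_cols(fA, fB[-1])
}
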