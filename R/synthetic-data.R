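# Synthetic-data generators: populations, pooled-array thetas and linkage maps
# with known truth, emulating a pooled-DNA SNP-array study of hierarchically
# differentiated populations.

#' Generate a random linkage map for a SNP panel
#'
#' Assigns loci uniformly at random to chromosomes and to map positions along
#' each chromosome. The map supports linkage-based pruning of ranked marker
#' panels (loci closer than a minimum centimorgan distance are treated as
#' linked).
#'
#' @param n_loci Number of loci.
#' @param n_chromosomes Number of chromosomes.
#' @param chrom_length_cM Chromosome length in centimorgans (all chromosomes
#'   share one length).
#' @param seed Integer seed; the map is deterministic given the seed.
#'
#' @return A tibble with columns `locus`, `chromosome`, `position_cM`, sorted
#'   by chromosome and position.
#' @export
#' @examples
#' generate_panel_map(10, n_chromosomes = 2, chrom_length_cM = 100, seed = 1)
generate_panel_map <- function(n_loci, n_chromosomes, chrom_length_cM,
                               seed = 1L) {
  n_loci <- check_count(n_loci, "n_loci")
  n_chromosomes <- check_count(n_chromosomes, "n_chromosomes")
  if (chrom_length_cM <= 0) abort("`chrom_length_cM` must be > 0")
  with_seed(seed, {
    map <- tibble::tibble(
      locus = locus_ids(n_loci),
      chromosome = sprintf("chr%02d", sample.int(n_chromosomes, n_loci,
                                                 replace = TRUE)),
      position_cM = runif(n_loci, 0, chrom_length_cM)
    )
  })
  dplyr::arrange(map, .data$chromosome, .data$position_cM)
}

#' Generate population allele frequencies under the Balding-Nichols F-model
#'
#' Each population's B-allele frequency at a locus is drawn from a Beta
#' distribution with mean equal to the locus's ancestral frequency and
#' variance `p(1-p) * F`, the standard F-model for populations diverged by
#' drift. A configured fraction of loci is planted as outliers whose
#' divergence parameter is multiplied by `outlier_multiplier`, mimicking
#' divergent selection that an outlier scan should recover.
#'
#' @param n_pops Number of populations.
#' @param n_loci Number of loci.
#' @param fst Per-population divergence parameter in (0, 0.5]; scalar or
#'   length-`n_pops` vector.
#' @param ancestral Optional vector of ancestral B-allele frequencies; by
#'   default drawn from Uniform(0.05, 0.95).
#' @param outlier_frac Fraction of loci planted as outliers (exact count
#'   `round(outlier_frac * n_loci)`).
#' @param outlier_multiplier Multiplier (> 1) applied to `fst` at outlier
#'   loci; the effective F must remain below 1.
#' @param seed Integer seed.
#'
#' @return A list of class `synthetic_freqs` with elements `freqs` (wide
#'   tibble: `locus` + one column per population) and `truth` (tibble:
#'   `locus`, `ancestral`, `outlier`).
#' @export
generate_population_frequencies <- function(n_pops, n_loci, fst,
                                            ancestral = NULL,
                                            outlier_frac = 0,
                                            outlier_multiplier = 1,
                                            seed = 1L) {
  n_pops <- check_count(n_pops, "n_pops")
  n_loci <- check_count(n_loci, "n_loci")
  fst <- rep_len(fst, n_pops)
  if (any(fst <= 0 | fst > 0.5)) abort("`fst` must lie in (0, 0.5]")
  if (outlier_frac < 0 || outlier_frac > 1) {
    abort("`outlier_frac` must lie in [0, 1]")
  }
  if (outlier_multiplier < 1) abort("`outlier_multiplier` must be >= 1")
  if (max(fst) * outlier_multiplier >= 1) {
    abort("effective F at outlier loci must stay below 1")
  }
  n_out <- round(outlier_frac * n_loci)
  with_seed(seed, {
    if (is.null(ancestral)) ancestral <- runif(n_loci, 0.05, 0.95)
    if (length(ancestral) != n_loci || any(ancestral <= 0 | ancestral >= 1)) {
      abort("`ancestral` must be length n_loci with values strictly in (0,1)")
    }
    outlier <- rep(FALSE, n_loci)
    if (n_out > 0) outlier[sample.int(n_loci, n_out)] <- TRUE
    p <- matrix(0, n_loci, n_pops, dimnames = list(locus_ids(n_loci),
                                                   pop_ids(n_pops)))
    for (j in seq_len(n_pops)) {
      f_eff <- ifelse(outlier, pmin(fst[j] * outlier_multiplier, 1 - 1e-9),
                      fst[j])
      shape <- (1 - f_eff) / f_eff
      p[, j] <- rbeta(n_loci, ancestral * shape, (1 - ancestral) * shape)
    }
  })
  structure(
    list(
      freqs = freq_tibble(p),
      truth = tibble::tibble(locus = rownames(p), ancestral = ancestral,
                             outlier = outlier)
    ),
    class = "synthetic_freqs"
  )
}

#' @export
print.synthetic_freqs <- function(x, ...) {
  cat(sprintf(
    "Synthetic allele frequencies: %d loci x %d populations (%d outlier loci)\n",
    nrow(x$freqs), ncol(x$freqs) - 1L, sum(x$truth$outlier)))
  invisible(x)
}

#' Generate per-locus genotype-cluster reference thetas
#'
#' On a two-colour SNP array the normalised signal (theta) of the AA, AB and
#' BB genotype clusters sits near, but not at, the theoretical 0, 0.5 and 1.
#' This generator jitters configurable cluster centres per locus with
#' independent Gaussian noise, clipping to \[0, 1\] and redrawing the rare
#' locus whose jittered values lose the strict AA < AB < BB ordering.
#'
#' @param n_loci Number of loci.
#' @param centers Length-3 numeric, cluster centres for (AA, AB, BB); must be
#'   strictly increasing within \[0, 1\].
#' @param jitter_sd Standard deviation of the per-locus Gaussian jitter.
#' @param seed Integer seed.
#' @param max_retries Redraw attempts per locus before failing.
#'
#' @return Tibble with columns `locus`, `theta_AA`, `theta_AB`, `theta_BB`.
#' @export
generate_cluster_reference <- function(n_loci,
                                       centers = c(0.05, 0.5, 0.95),
                                       jitter_sd = 0.02, seed = 1L,
                                       max_retries = 100L) {
  n_loci <- check_count(n_loci, "n_loci")
  if (length(centers) != 3 || any(diff(centers) <= 0) ||
      centers[1] < 0 || centers[3] > 1) {
    abort("`centers` must be three strictly increasing values in [0, 1]")
  }
  if (jitter_sd < 0) abort("`jitter_sd` must be >= 0")
  with_seed(seed, {
    draw <- function(n) {
      cbind(pmin(pmax(centers[1] + rnorm(n, 0, jitter_sd), 0), 1),
            pmin(pmax(centers[2] + rnorm(n, 0, jitter_sd), 0), 1),
            pmin(pmax(centers[3] + rnorm(n, 0, jitter_sd), 0), 1))
    }
    th <- draw(n_loci)
    for (i in seq_len(max_retries)) {
      bad <- which(th[, 1] >= th[, 2] | th[, 2] >= th[, 3])
      if (!length(bad)) break
      th[bad, ] <- draw(length(bad))
    }
  })
  if (any(th[, 1] >= th[, 2] | th[, 2] >= th[, 3])) {
    abort("could not generate strictly ordered cluster thetas; reduce jitter_sd")
  }
  tibble::tibble(locus = locus_ids(n_loci), theta_AA = th[, 1],
                 theta_AB = th[, 2], theta_BB = th[, 3])
}

# Inverse of the piecewise-linear theta correction: map a B-allele frequency
# back to the array theta that `theta_to_frequency()` would convert to it.
frequency_to_theta <- function(freq, ref_AA, ref_AB, ref_BB) {
  ifelse(freq <= 0.5,
         ref_AA + 2 * freq * (ref_AB - ref_AA),
         ref_AB + 2 * (freq - 0.5) * (ref_BB - ref_AB))
}

#' Simulate technical pool replicates of array thetas
#'
#' For each population x locus cell the noiseless theta is the exact inverse
#' of the piecewise-linear cluster correction applied by
#' [theta_to_frequency()], so at zero noise the allelotyping round trip
#' returns the input frequencies exactly. Gaussian measurement noise is added
#' per replicate and truncated to \[0, 1\].
#'
#' @param freqs Wide frequency tibble (`locus` + population columns), e.g.
#'   `generate_population_frequencies(...)$freqs`.
#' @param ref Cluster-reference tibble as from [generate_cluster_reference()];
#'   must cover all loci of `freqs`.
#' @param n_replicates Number of technical replicates (1--10; studies of this
#'   design typically use 3--6).
#' @param theta_noise_sd Standard deviation of the replicate noise.
#' @param seed Integer seed.
#'
#' @return Long tibble with columns `population`, `locus`, `replicate`,
#'   `theta`.
#' @export
generate_pool_replicates <- function(freqs, ref, n_replicates = 4L,
                                     theta_noise_sd = 0.01, seed = 1L) {
  n_replicates <- check_count(n_replicates, "n_replicates")
  if (n_replicates > 10L) abort("`n_replicates` must be in [1, 10]")
  if (theta_noise_sd < 0) abort("`theta_noise_sd` must be >= 0")
  p <- freq_matrix(freqs)
  ref <- ref[match(rownames(p), ref$locus), ]
  if (anyNA(ref$locus)) abort("cluster reference does not cover all loci")
  pops <- colnames(p)
  base <- frequency_to_theta(p, ref$theta_AA, ref$theta_AB, ref$theta_BB)
  with_seed(seed, {
    reps <- purrr::map_dfr(seq_len(n_replicates), function(r) {
      th <- base + rnorm(length(base), 0, theta_noise_sd)
      th <- pmin(pmax(th, 0), 1)
      tibble::tibble(
        population = rep(pops, each = nrow(p)),
        locus = rep(rownames(p), times = length(pops)),
        replicate = r,
        theta = as.vector(th)
      )
    })
  })
  dplyr::arrange(reps, .data$population, .data$locus, .data$replicate)
}

#' Generate multiallelic (STR-like) population allele frequencies
#'
#' Dirichlet analogue of the Balding-Nichols model: each population's
#' allele-frequency vector at a locus is drawn from a Dirichlet centred on a
#' random ancestral simplex point with concentration `(1 - F) / F`, so the
#' among-population differentiation matches the target F. Used for
#' independent-allele comparisons between SNP and microsatellite panels.
#'
#' @param n_pops Number of populations.
#' @param alleles_per_locus Integer vector (one entry per locus) of allele
#'   counts, each >= 2.
#' @param fst Divergence parameter in (0, 1).
#' @param seed Integer seed.
#'
#' @return Long tibble with columns `locus`, `allele`, then one frequency
#'   column per population; frequencies sum to 1 within locus and population.
#' @export
generate_multiallelic_loci <- function(n_pops, alleles_per_locus, fst,
                                       seed = 1L) {
  n_pops <- check_count(n_pops, "n_pops")
  if (any(alleles_per_locus < 2)) abort("each locus needs >= 2 alleles")
  if (fst <= 0 || fst >= 1) abort("`fst` must lie in (0, 1)")
  n_loci <- length(alleles_per_locus)
  conc <- (1 - fst) / fst
  rdirichlet <- function(alpha) {
    g <- rgamma(length(alpha), shape = alpha, rate = 1)
    g / sum(g)
  }
  with_seed(seed, {
    out <- purrr::map_dfr(seq_len(n_loci), function(l) {
      k <- alleles_per_locus[l]
      anc <- rdirichlet(rep(1, k))
      popfreq <- vapply(seq_len(n_pops),
                        function(j) rdirichlet(conc * anc),
                        numeric(k))
      colnames(popfreq) <- pop_ids(n_pops)
      dplyr::bind_cols(
        tibble::tibble(locus = sprintf("STR%03d", l),
                       allele = sprintf("a%02d", seq_len(k))),
        tibble::as_tibble(popfreq)
      )
    })
  })
  out
}
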