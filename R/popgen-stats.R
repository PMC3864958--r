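# Frequency-based population-genetic summaries: expected heterozygosity,
# Weir-Cockerham F_ST (global and pairwise), Delta allele-frequency
# differentials and Nei's D_A distance.

#' Expected heterozygosity from allele frequencies
#'
#' Biallelic loci use `He = 2p(1-p)`; multiallelic (long-format) tables use
#' `He = 1 - sum(p^2)`.
#'
#' @param freqs Wide biallelic frequency tibble (`locus` + population
#'   columns) or a long multiallelic table with `locus`, `allele` and
#'   population columns (as from [generate_multiallelic_loci()]).
#'
#' @return A list of class `he_summary`: `per_locus` (long tibble `locus`,
#'   `population`, `he`), `per_population` (tibble `population`, `mean_he`,
#'   `median_he`).
#' @export
expected_heterozygosity <- function(freqs) {
  if ("allele" %in% names(freqs)) {
    pops <- setdiff(names(freqs), c("locus", "allele"))
    per_locus <- freqs %>%
      tidyr::pivot_longer(dplyr::all_of(pops), names_to = "population",
                          values_to = "freq") %>%
      dplyr::group_by(.data$locus, .data$population) %>%
      dplyr::summarise(he = 1 - sum(.data$freq^2), .groups = "drop")
  } else {
    p <- freq_matrix(freqs)
    per_locus <- freq_tibble(2 * p * (1 - p)) %>%
      tidyr::pivot_longer(-"locus", names_to = "population",
                          values_to = "he")
  }
  per_population <- per_locus %>%
    dplyr::group_by(.data$population) %>%
    dplyr::summarise(mean_he = mean(.data$he), median_he = median(.data$he),
                     .groups = "drop")
  structure(list(per_locus = per_locus, per_population = per_population),
            class = "he_summary")
}

#' @export
print.he_summary <- function(x, ...) {
  cat("Expected heterozygosity by population:\n")
  print(x$per_population, ...)
  invisible(x)
}

# Weir-Cockerham variance-components F_ST from allele frequencies p
# (loci x pops) and per-population gene-copy counts n.
#
# With sampling_correction = TRUE this is the classic estimator for sample
# frequencies carrying binomial noise of depth n: the within-population mean
# square is subtracted from the among-population mean square.  Pool
# frequencies, however, estimate the population frequency directly (their
# noise is technical, not binomial), so subtracting MSG over-corrects by
# ~(1-F)/(2n); the default keeps the variance decomposition but drops the
# numerator subtraction, which is unbiased for the divergence parameter when
# frequencies are exact.  Monomorphic-everywhere loci are NA.
wc_theta <- function(p, n_copies, sampling_correction = FALSE) {
  r <- ncol(p)
  if (r < 2) abort("F_ST requires at least 2 populations")
  N <- sum(n_copies)
  n_c <- (N - sum(n_copies^2) / N) / (r - 1)
  pbar <- as.vector(p %*% n_copies) / N
  msp <- as.vector(((p - pbar)^2) %*% n_copies) / (r - 1)
  msg <- as.vector((p * (1 - p)) %*% n_copies) / (N - r)
  num <- if (sampling_correction) msp - msg else msp
  den <- msp + (n_c - 1) * msg
  ifelse(den > 0, num / den, NA_real_)
}

#' Global F_ST over all populations
#'
#' Per-locus Weir-Cockerham variance-components estimator computed from
#' population allele frequencies, treating each pool as a sample of
#' `2 * n_ind` gene copies. Negative per-locus estimates are retained (they
#' keep multi-locus averages unbiased); truncate for display only. Loci
#' monomorphic in every population have no defined estimate and are `NA`.
#'
#' @param freqs Wide frequency tibble (`locus` + population columns).
#' @param n_ind Pool size in diploid individuals; scalar or named
#'   per-population vector. Default 50.
#' @param sampling_correction Subtract the within-population (binomial
#'   sampling) mean square from the numerator, as in the classic estimator
#'   for sample frequencies. Pool frequencies estimate the population
#'   frequency directly, so the default `FALSE` keeps the variance
#'   decomposition without that subtraction, which is calibrated for
#'   frequencies measured without genotype-sampling noise.
#'
#' @return Tibble `locus`, `fst` with attributes `mean`, `median` (over
#'   defined loci) and `overall` (ratio-of-sums multi-locus estimate).
#' @export
fst_global <- function(freqs, n_ind = 50, sampling_correction = FALSE) {
  p <- freq_matrix(freqs)
  n_copies <- gene_copies(n_ind, colnames(p))
  theta <- wc_theta(p, n_copies, sampling_correction)
  out <- tibble::tibble(locus = rownames(p), fst = theta)
  ok <- !is.na(theta)
  attr(out, "mean") <- mean(theta[ok])
  attr(out, "median") <- median(theta[ok])
  # ratio-of-sums multilocus estimate over defined loci
  r <- ncol(p)
  N <- sum(n_copies)
  n_c <- (N - sum(n_copies^2) / N) / (r - 1)
  pbar <- as.vector(p %*% n_copies) / N
  msp <- as.vector(((p - pbar)^2) %*% n_copies) / (r - 1)
  msg <- as.vector((p * (1 - p)) %*% n_copies) / (N - r)
  num <- if (sampling_correction) msp - msg else msp
  attr(out, "overall") <- sum(num[ok]) / sum(msp[ok] + (n_c - 1) * msg[ok])
  out
}

#' Pairwise F_ST between populations
#'
#' Applies the same Weir-Cockerham estimator as [fst_global()] to every
#' unordered pair of populations.
#'
#' @inheritParams fst_global
#'
#' @return A list of class `pairwise_fst`: `pairs` (tibble `pop_i`, `pop_j`,
#'   `fst` = mean of per-locus estimates over defined loci), `per_locus`
#'   (tibble `locus`, `fst_pairwise_mean` = per-locus mean over pairs).
#' @export
fst_pairwise <- function(freqs, n_ind = 50, sampling_correction = FALSE) {
  p <- freq_matrix(freqs)
  pops <- colnames(p)
  n_copies <- gene_copies(n_ind, pops)
  pr <- utils::combn(pops, 2)
  per_pair_locus <- matrix(NA_real_, nrow(p), ncol(pr))
  pair_mean <- numeric(ncol(pr))
  for (k in seq_len(ncol(pr))) {
    sel <- pr[, k]
    th <- wc_theta(p[, sel, drop = FALSE], n_copies[sel], sampling_correction)
    per_pair_locus[, k] <- th
    pair_mean[k] <- mean(th, na.rm = TRUE)
  }
  structure(
    list(
      pairs = tibble::tibble(pop_i = pr[1, ], pop_j = pr[2, ],
                             fst = pair_mean),
      per_locus = tibble::tibble(
        locus = rownames(p),
        fst_pairwise_mean = rowMeans(per_pair_locus, na.rm = TRUE)
      )
    ),
    class = "pairwise_fst"
  )
}

#' @export
print.pairwise_fst <- function(x, ...) {
  cat(sprintf("Pairwise F_ST over %d population pairs (range %.3f - %.3f)\n",
              nrow(x$pairs), min(x$pairs$fst), max(x$pairs$fst)))
  invisible(x)
}

#' Delta: mean absolute allele-frequency differential
#'
#' For a biallelic locus, Delta between two populations is `|p_i - p_j|`;
#' the per-locus score is the mean over all unordered population pairs.
#'
#' @param freqs Wide frequency tibble (`locus` + population columns).
#'
#' @return Tibble `locus`, `delta` with values in \[0, 1\].
#' @export
delta_differential <- function(freqs) {
  p <- freq_matrix(freqs)
  if (ncol(p) < 2) abort("Delta requires at least 2 populations")
  pairs <- utils::combn(ncol(p), 2)
  acc <- rowSums(abs(p[, pairs[1, ], drop = FALSE] -
                     p[, pairs[2, ], drop = FALSE]))
  tibble::tibble(locus = rownames(p), delta = unname(acc) / ncol(pairs))
}

#' Nei's D_A genetic distance between populations
#'
#' `D_A(i, j) = 1 - mean over loci of sum over alleles of sqrt(p_i * p_j)`.
#' For biallelic input both alleles (p and 1-p) enter the allele-sharing
#' term.
#'
#' @param freqs Wide biallelic frequency tibble, or a long multiallelic
#'   table with `locus`, `allele` and population columns.
#'
#' @return Symmetric population x population distance matrix (zero
#'   diagonal), values in \[0, 1\].
#' @export
nei_da <- function(freqs) {
  if ("allele" %in% names(freqs)) {
    pops <- setdiff(names(freqs), c("locus", "allele"))
    sq <- sqrt(as.matrix(freqs[pops]))
    loci <- freqs$locus
  } else {
    p <- freq_matrix(freqs)
    pops <- colnames(p)
    sq <- rbind(sqrt(p), sqrt(1 - p))
    loci <- c(rownames(p), rownames(p))
  }
  n_loci <- length(unique(loci))
  k <- length(pops)
  d <- matrix(0, k, k, dimnames = list(pops, pops))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      share <- sum(sq[, i] * sq[, j]) / n_loci
      d[i, j] <- d[j, i] <- max(0, 1 - share)
    }
  }
  d
}
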