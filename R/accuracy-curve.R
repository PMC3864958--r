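# Assignment-accuracy curves over marker-subset sizes and the exponential
# marker-requirement fit.

#' Assignment accuracy as a function of marker-panel size
#'
#' For each subset size: take the top loci of the ranking (or a random
#' subset), simulate a disjoint baseline (default 100 genotypes per
#' population) and mixture (default 500 per population) under HWE/LE,
#' estimate the stock composition by EM, assign every mixture individual
#' with the mixture-proportion prior, and record overall and per-population
#' percent-correct. Baseline individuals are never removed from their own
#' baseline; as in the underlying study design this makes accuracies
#' somewhat optimistic.
#'
#' @inheritParams fst_global
#' @param ranking `locus_ranking` tibble (already pruned if linkage pruning
#'   is wanted), or a plain character vector of loci in rank order.
#' @param sizes Subset sizes to evaluate (strictly positive, at most the
#'   ranking length).
#' @param n_baseline,n_mixture Simulated individuals per population for the
#'   baseline and mixture samples.
#' @param mixture_props Optional named per-population weights for the
#'   mixture composition (default uniform); rescaled to per-population
#'   counts summing approximately to `n_mixture * n_pops`.
#' @param random Evaluate random subsets instead of top-ranked ones.
#' @param seed Integer seed; each subset size uses an independent derived
#'   seed so curves are reproducible point by point.
#'
#' @return Tibble of class `accuracy_curve`: `size`,
#'   `independent_alleles`, `overall_pct`, and a nested `per_population`
#'   list-column; attribute `meta` records the design.
#' @export
accuracy_curve <- function(freqs, ranking, sizes = c(25, 50, 75, 100, 125,
                                                     150, 200, 250, 300),
                           n_baseline = 100L, n_mixture = 500L,
                           mixture_props = NULL, random = FALSE, seed = 1L) {
  loci_ranked <- if (is.data.frame(ranking)) ranking$locus else ranking
  sizes <- sort(unique(as.integer(sizes)))
  if (any(sizes < 1)) abort("subset sizes must be >= 1")
  if (max(sizes) > length(loci_ranked)) {
    abort(sprintf("largest size (%d) exceeds ranked loci (%d)",
                  max(sizes), length(loci_ranked)))
  }
  pops <- setdiff(names(freqs), "locus")
  n_mix <- if (is.null(mixture_props)) {
    setNames(rep(n_mixture, length(pops)), pops)
  } else {
    w <- mixture_props[pops] / sum(mixture_props[pops])
    setNames(round(w * n_mixture * length(pops)), pops)
  }
  seeds <- derive_seeds(seed, 3L)
  pool <- if (random) {
    with_seed(seeds[3], sample(loci_ranked, max(sizes)))
  } else {
    loci_ranked[seq_len(max(sizes))]
  }
  rows <- purrr::map(seq_along(sizes), function(k) {
    loci <- pool[seq_len(sizes[k])]
    base <- simulate_genotypes(freqs, n_baseline, loci = loci,
                               role = "baseline", seed = seeds[1] + k)
    mix <- simulate_genotypes(freqs, n_mix, loci = loci, role = "mixture",
                              seed = seeds[2] + k)
    bl <- baseline_counts(base)
    acc <- evaluate_accuracy(gsi_assign(mix, bl, prior = "mixture"))
    tibble::tibble(
      size = sizes[k],
      independent_alleles = sizes[k],  # biallelic SNP panels: k - 1 = 1
      overall_pct = acc$overall_pct,
      per_population = list(acc$per_population)
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("accuracy_curve", class(out))
  attr(out, "meta") <- list(n_baseline = n_baseline, n_mixture = n_mix,
                            random = random, seed = seed)
  out
}

#' Fit the exponential marker-requirement model
#'
#' Fits `y = exp(a + b / x)` to (panel size, percent correct) points by
#' least squares on the linearised form `log y = a + b / x`, and inverts the
#' fit to the number of markers needed for each target accuracy:
#' `required_x(t) = ceiling(b / (log t - a))`, defined only when the target
#' lies below the fitted asymptote `exp(a)` and `b < 0`. A flat curve
#' (`b >= 0` within tolerance) reports every attained target at the
#' smallest observed panel size.
#'
#' @param curve `accuracy_curve` tibble, or any data frame with columns
#'   `independent_alleles` (or `size`) and `overall_pct`.
#' @param targets Target percent-correct levels (default 80, 90, 95).
#'
#' @return Object of class `marker_fit`: `a`, `b`, `required` (tibble
#'   `target_pct`, `required_markers`, `attainable`), `fitted` (input points
#'   with fitted values).
#' @export
fit_required_markers <- function(curve, targets = c(80, 90, 95)) {
  x <- if ("independent_alleles" %in% names(curve)) {
    curve$independent_alleles
  } else curve$size
  y <- curve$overall_pct
  if (length(x) < 3) abort("need at least 3 curve points")
  if (any(y <= 0)) abort("percent-correct values must be > 0")
  fit <- lm(log(y) ~ I(1 / x))
  a <- unname(coef(fit)[1])
  b <- unname(coef(fit)[2])
  flat <- b >= -1e-10
  if (flat && b > 1e-10) {
    warn("fitted b >= 0: accuracy does not increase with panel size; targets marked by observation only")
  }
  required <- purrr::map_dfr(targets, function(t) {
    if (flat) {
      attained <- t <= max(y) + 1e-9
      tibble::tibble(target_pct = t,
                     required_markers = if (attained) min(x) else NA_real_,
                     attainable = attained)
    } else if (log(t) >= a) {
      tibble::tibble(target_pct = t, required_markers = NA_real_,
                     attainable = FALSE)
    } else {
      tibble::tibble(target_pct = t,
                     required_markers = ceiling(b / (log(t) - a)),
                     attainable = TRUE)
    }
  })
  structure(
    list(a = a, b = b, required = required,
         fitted = tibble::tibble(x = x, y = y,
                                 y_fit = exp(a + b / x))),
    class = "marker_fit"
  )
}

#' @export
print.marker_fit <- function(x, ...) {
  cat(sprintf("Exponential marker-requirement fit: y = exp(%.4f %+.2f / x); asymptote %.1f%%\n",
              x$a, x$b, exp(x$a)))
  print(x$required)
  invisible(x)
}

#' @describeIn fit_required_markers Tidy the solved marker requirements.
#' @param x A `marker_fit` object.
#' @param ... Unused.
#' @export
tidy.marker_fit <- function(x, ...) x$required

#' @describeIn fit_required_markers One-row fit summary (a, b, asymptote,
#'   residual SD on the log scale).
#' @export
glance.marker_fit <- function(x, ...) {
  tibble::tibble(
    a = x$a, b = x$b, asymptote_pct = exp(x$a),
    sigma_log = sqrt(mean((log(x$fitted$y) - log(x$fitted$y_fit))^2)),
    n_points = nrow(x$fitted)
  )
}
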