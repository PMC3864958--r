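# Allelotyping: converting pooled-DNA array thetas to population allele
# frequencies with genotype-cluster correction and replicate quality control.

#' Convert an array theta to a B-allele frequency
#'
#' Piecewise-linear cluster correction: the pool's theta is interpolated
#' between the per-locus mean thetas of the AA, AB and BB genotype clusters
#' (estimated from individually genotyped reference samples). Thetas at or
#' below the AA cluster map to frequency 0, at the AB cluster to 0.5, at or
#' above the BB cluster to 1, with linear interpolation in between.
#'
#' All arguments are vectorised and recycled.
#'
#' @param theta Pool theta value(s) in \[0, 1\].
#' @param ref_AA,ref_AB,ref_BB Cluster mean thetas, strictly increasing per
#'   locus.
#' @param locus Optional locus ids used in error messages.
#'
#' @return B-allele frequency in \[0, 1\], same length as the longest input.
#' @export
#' @examples
#' theta_to_frequency(0.715, 0.05, 0.48, 0.95)  # 0.75
theta_to_frequency <- function(theta, ref_AA, ref_AB, ref_BB, locus = NULL) {
  n <- max(length(theta), length(ref_AA), length(ref_AB), length(ref_BB))
  theta <- rep_len(theta, n)
  ref_AA <- rep_len(ref_AA, n)
  ref_AB <- rep_len(ref_AB, n)
  ref_BB <- rep_len(ref_BB, n)
  bad <- which(ref_AA >= ref_AB | ref_AB >= ref_BB)
  if (length(bad)) {
    lab <- if (!is.null(locus)) rep_len(locus, n)[bad[1]] else bad[1]
    abort(sprintf("cluster thetas not strictly ordered (AA < AB < BB) at locus %s",
                  lab))
  }
  lower <- 0.5 * (theta - ref_AA) / (ref_AB - ref_AA)
  upper <- 0.5 + 0.5 * (theta - ref_AB) / (ref_BB - ref_AB)
  out <- ifelse(theta <= ref_AB, lower, upper)
  pmin(pmax(out, 0), 1)
}

#' Replicate quality control for pooled thetas
#'
#' Computes the standard deviation of theta across technical replicates for
#' every population x locus cell and retains a locus panel-wide only when
#' every population's replicate SD is at or below `max_sd`. A single
#' replicate gives SD 0 (with a warning), matching the convention that a
#' lone measurement cannot demonstrate irreproducibility.
#'
#' @param thetas Long replicate tibble with columns `population`, `locus`,
#'   `replicate`, `theta` (as from [generate_pool_replicates()] or
#'   [read_theta_replicates()]).
#' @param max_sd Maximum tolerated replicate standard deviation
#'   (default 0.02).
#'
#' @return A list of class `pool_qc`: `flags` (tibble `population`, `locus`,
#'   `n_replicates`, `rep_sd`, `pass`), `retained` (character vector of loci
#'   passing in every population), `n_dropped` (count of dropped loci).
#' @export
filter_replicate_quality <- function(thetas, max_sd = 0.02) {
  if (max_sd <= 0) abort("`max_sd` must be > 0")
  check_theta_long(thetas)
  flags <- thetas %>%
    dplyr::group_by(.data$population, .data$locus) %>%
    dplyr::summarise(
      n_replicates = dplyr::n(),
      rep_sd = if (dplyr::n() > 1) sd(.data$theta) else 0,
      .groups = "drop"
    ) %>%
    dplyr::mutate(pass = .data$rep_sd <= .env$max_sd)
  if (any(flags$n_replicates == 1L)) {
    warn("some population x locus cells have a single replicate; their SD is taken as 0")
  }
  by_locus <- flags %>%
    dplyr::group_by(.data$locus) %>%
    dplyr::summarise(keep = all(.data$pass), .groups = "drop")
  retained <- by_locus$locus[by_locus$keep]
  structure(
    list(flags = flags, retained = retained,
         n_dropped = sum(!by_locus$keep), max_sd = max_sd),
    class = "pool_qc"
  )
}

#' @export
print.pool_qc <- function(x, ...) {
  total <- length(x$retained) + x$n_dropped
  cat(sprintf(
    "Replicate QC (max SD %.3g): %d / %d loci retained (%d dropped)\n",
    x$max_sd, length(x$retained), total, x$n_dropped))
  invisible(x)
}

#' Estimate population allele frequencies from pooled thetas
#'
#' Converts each technical replicate's theta to a B-allele frequency via the
#' piecewise-linear cluster correction, then averages the per-replicate
#' frequencies within each population x locus cell. Conversion happens before
#' averaging; because the correction is piecewise linear the two orders
#' differ only when replicates straddle the heterozygote cluster, and
#' converting first keeps each replicate's estimate on the frequency scale
#' the downstream statistics use.
#'
#' @param thetas Long replicate tibble (`population`, `locus`, `replicate`,
#'   `theta`).
#' @param ref Cluster-reference tibble (`locus`, `theta_AA`, `theta_AB`,
#'   `theta_BB`) covering all loci in `thetas`.
#' @param qc Optional `pool_qc` object from [filter_replicate_quality()];
#'   when supplied only its retained loci are estimated.
#'
#' @return Wide frequency tibble: `locus` column plus one column per
#'   population, values in \[0, 1\].
#' @export
pool_frequencies <- function(thetas, ref, qc = NULL) {
  check_theta_long(thetas)
  if (!is.null(qc)) {
    if (!inherits(qc, "pool_qc")) abort("`qc` must come from filter_replicate_quality()")
    thetas <- dplyr::filter(thetas, .data$locus %in% qc$retained)
    if (nrow(thetas) == 0L) abort("no loci left after replicate QC")
  }
  idx <- match(thetas$locus, ref$locus)
  if (anyNA(idx)) {
    abort(sprintf("locus '%s' has no cluster reference",
                  thetas$locus[which(is.na(idx))[1]]))
  }
  est <- thetas %>%
    dplyr::mutate(freq = theta_to_frequency(.data$theta,
                                            ref$theta_AA[idx],
                                            ref$theta_AB[idx],
                                            ref$theta_BB[idx],
                                            locus = .data$locus)) %>%
    dplyr::group_by(.data$population, .data$locus) %>%
    dplyr::summarise(freq = mean(.data$freq), .groups = "drop") %>%
    tidyr::pivot_wider(names_from = "population", values_from = "freq")
  dplyr::arrange(est, .data$locus)
}

check_theta_long <- function(thetas) {
  need <- c("population", "locus", "replicate", "theta")
  if (!is.data.frame(thetas) || !all(need %in% names(thetas))) {
    abort("`thetas` must be a data frame with columns population, locus, replicate, theta")
  }
  if (any(thetas$theta < 0 | thetas$theta > 1)) {
    abort("theta values must lie in [0, 1]")
  }
  invisible(thetas)
}
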