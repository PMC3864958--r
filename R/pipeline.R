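# End-to-end orchestration: allelotyping (when thetas are supplied),
# population summaries, marker ranking across population datasets, accuracy
# curves and marker-requirement fits.

#' Run the pooled-DNA marker-selection and GSI pipeline
#'
#' Orchestrates the full workflow on one frequency table: optional
#' allelotyping from replicate thetas (with replicate QC), per-locus
#' divergence scores, rankings per method and population dataset, optional
#' linkage pruning and outlier scanning, assignment-accuracy curves for
#' ranked and random panels, and exponential marker-requirement fits.
#'
#' @param freqs Wide frequency tibble; ignored when `thetas` and
#'   `cluster_ref` are given (frequencies are then estimated from pools).
#' @param thetas Optional long replicate-theta tibble.
#' @param cluster_ref Cluster reference, required with `thetas`.
#' @param map Optional linkage map for `> min_cM` pruning of ranked panels.
#' @param n_ind Pool size (diploid individuals) per population.
#' @param datasets Named list of population subsets to rank on; default one
#'   dataset `"I"` with all populations.
#' @param methods Ranking methods to run (subset of `"global_fst"`,
#'   `"pairwise_fst"`, `"delta"`, `"outlier"`).
#' @param sizes Subset sizes for the accuracy curves.
#' @param max_sd Replicate-QC threshold on theta SD.
#' @param min_cM Linkage-pruning distance; `NULL` skips pruning.
#' @param n_baseline,n_mixture Simulated individuals per population.
#' @param mcmc MCMC settings for the outlier scan (see [scan_outliers()]).
#' @param out_dir Optional directory; when given, every artifact is written
#'   as TSV with a provenance header.
#' @param seed Integer seed; stage seeds are derived from it.
#'
#' @return Named list: `freqs`, `qc` (or NULL), `divergence`, `rankings`
#'   (nested by dataset then method), `outliers` (by dataset, if run),
#'   `curves`, `fits`, `tree`.
#' @export
gsi_pipeline <- function(freqs = NULL, thetas = NULL, cluster_ref = NULL,
                         map = NULL, n_ind = 50,
                         datasets = NULL,
                         methods = c("pairwise_fst", "delta"),
                         sizes = c(25, 50, 75, 100, 150, 200, 250, 300),
                         max_sd = 0.02, min_cM = 1.0,
                         n_baseline = 100L, n_mixture = 500L,
                         mcmc = list(), out_dir = NULL, seed = 1L) {
  seeds <- derive_seeds(seed, 4L)
  qc <- NULL
  if (!is.null(thetas)) {
    if (is.null(cluster_ref)) abort("`cluster_ref` is required with `thetas`")
    qc <- filter_replicate_quality(thetas, max_sd = max_sd)
    freqs <- pool_frequencies(thetas, cluster_ref, qc = qc)
  }
  if (is.null(freqs)) abort("supply `freqs`, or `thetas` with `cluster_ref`")
  pops <- setdiff(names(freqs), "locus")
  if (is.null(datasets)) datasets <- list(I = pops)
  bad <- setdiff(unlist(datasets), pops)
  if (length(bad)) {
    abort(paste0("datasets reference unknown populations: ", toString(bad)))
  }

  rankings <- list()
  outliers <- list()
  for (ds in names(datasets)) {
    sub <- freqs[c("locus", datasets[[ds]])]
    div <- locus_divergence(sub, n_ind = n_ind)
    rankings[[ds]] <- list()
    for (m in setdiff(methods, "outlier")) {
      r <- rank_loci(div, method = m)
      if (!is.null(map) && !is.null(min_cM)) r <- prune_linked(r, map, min_cM)
      rankings[[ds]][[m]] <- r
    }
    if ("outlier" %in% methods) {
      sc <- scan_outliers(sub, n_ind = n_ind, mcmc = mcmc, seed = seeds[2])
      outliers[[ds]] <- sc
      r <- rank_loci(sc, method = "outlier")
      if (!is.null(map) && !is.null(min_cM)) r <- prune_linked(r, map, min_cM)
      rankings[[ds]][["outlier"]] <- r
    }
  }

  divergence <- locus_divergence(freqs, n_ind = n_ind)
  tree <- nj_tree(nei_da(freqs))

  curves <- list()
  fits <- list()
  ds1 <- names(datasets)[1]
  for (m in names(rankings[[ds1]])) {
    curves[[m]] <- accuracy_curve(freqs, rankings[[ds1]][[m]], sizes = sizes,
                                  n_baseline = n_baseline,
                                  n_mixture = n_mixture, seed = seeds[3])
    fits[[m]] <- fit_required_markers(curves[[m]])
  }
  curves[["random"]] <- accuracy_curve(freqs, divergence$locus, sizes = sizes,
                                       n_baseline = n_baseline,
                                       n_mixture = n_mixture, random = TRUE,
                                       seed = seeds[4])
  fits[["random"]] <- fit_required_markers(curves[["random"]])

  out <- list(freqs = freqs, qc = qc, divergence = divergence,
              rankings = rankings, outliers = outliers, curves = curves,
              fits = fits, tree = tree)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_freq_table(freqs, file.path(out_dir, "allele_frequencies.tsv"),
                     seed = seed)
    write_tsv_prov(divergence, file.path(out_dir, "locus_divergence.tsv"),
                   seed = seed)
    for (ds in names(rankings)) {
      for (m in names(rankings[[ds]])) {
        write_tsv_prov(rankings[[ds]][[m]],
                       file.path(out_dir, sprintf("ranking_%s_%s.tsv", ds, m)),
                       seed = seed)
      }
    }
    for (m in names(curves)) {
      write_tsv_prov(dplyr::select(curves[[m]], -"per_population"),
                     file.path(out_dir, sprintf("accuracy_curve_%s.tsv", m)),
                     seed = seed)
    }
    ape::write.tree(tree, file.path(out_dir, "nj_tree.nwk"))
  }
  out
}
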