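# Marker-informativeness ranking: divergence scores, upper-quartile
# classification, linkage pruning and top-K / random subset construction.

#' Per-locus divergence score table
#'
#' Computes the three frequency-based informativeness scores in one pass:
#' global F_ST, per-locus mean pairwise F_ST, and Delta (mean absolute
#' pairwise frequency differential). This is the input to [rank_loci()].
#'
#' @inheritParams fst_global
#'
#' @return Tibble `locus`, `fst_global`, `fst_pairwise_mean`, `delta`.
#'   Loci monomorphic in every population carry `NA` F_ST values.
#' @export
locus_divergence <- function(freqs, n_ind = 50) {
  g <- fst_global(freqs, n_ind)
  pw <- fst_pairwise(freqs, n_ind)
  d <- delta_differential(freqs)
  tibble::tibble(
    locus = g$locus,
    fst_global = g$fst,
    fst_pairwise_mean = pw$per_locus$fst_pairwise_mean[match(g$locus, pw$per_locus$locus)],
    delta = d$delta[match(g$locus, d$locus)]
  )
}

#' Rank loci by an informativeness score
#'
#' Descending sort by the chosen method's score, ties broken by locus id so
#' the ordering is deterministic. Loci with undefined scores (monomorphic
#' everywhere) rank last.
#'
#' @param divergence Divergence table from [locus_divergence()], or for
#'   `method = "outlier"` an outlier-scan result from [scan_outliers()].
#' @param method One of `"global_fst"`, `"pairwise_fst"`, `"delta"`,
#'   `"outlier"`.
#'
#' @return A tibble of class `locus_ranking`: `rank`, `locus`, `score`,
#'   `method`, best first.
#' @export
rank_loci <- function(divergence, method = c("global_fst", "pairwise_fst",
                                             "delta", "outlier")) {
  method <- match.arg(method)
  col <- switch(method,
                global_fst = "fst_global",
                pairwise_fst = "fst_pairwise_mean",
                delta = "delta",
                outlier = "log10_po")
  if (!col %in% names(divergence)) {
    abort(sprintf("`divergence` lacks column '%s' required by method '%s'",
                  col, method))
  }
  out <- tibble::tibble(locus = divergence$locus,
                        score = divergence[[col]]) %>%
    dplyr::arrange(dplyr::desc(!is.na(.data$score)),
                   dplyr::desc(.data$score), .data$locus) %>%
    dplyr::mutate(rank = dplyr::row_number(), method = .env$method) %>%
    dplyr::select("rank", "locus", "score", "method")
  class(out) <- c("locus_ranking", class(out))
  out
}

#' Flag loci in the upper quartile of a divergence distribution
#'
#' A locus is classified as showing a high level of differentiation when its
#' score is at or above the 75th percentile (linear-interpolation quantile,
#' R type 7) of the score distribution.
#'
#' @param scores Numeric vector of divergence scores (`NA` allowed; never
#'   flagged).
#'
#' @return Logical vector, `TRUE` for upper-quartile loci.
#' @export
classify_upper_quartile <- function(scores) {
  ok <- !is.na(scores)
  if (sum(ok) < 4) abort("need at least 4 loci with defined scores")
  thr <- quantile(scores[ok], 0.75, type = 7, names = FALSE)
  !is.na(scores) & scores >= thr
}

#' Prune linked loci from a ranking
#'
#' Greedy scan from best- to worst-ranked locus, keeping a locus only when
#' its map distance to every already-kept locus on the same chromosome
#' exceeds `min_cM`. Loci absent from the map are treated as unlinked and
#' kept, with a warning.
#'
#' @param ranking `locus_ranking` tibble from [rank_loci()].
#' @param map Linkage map tibble (`locus`, `chromosome`, `position_cM`).
#' @param min_cM Minimum distance (centimorgans) between kept loci
#'   (default 1).
#'
#' @return The pruned ranking (same columns, ranks renumbered).
#' @export
prune_linked <- function(ranking, map, min_cM = 1.0) {
  idx <- match(ranking$locus, map$locus)
  if (anyNA(idx)) {
    warn(sprintf("%d ranked loci absent from the map are treated as unlinked",
                 sum(is.na(idx))))
  }
  chrom <- map$chromosome[idx]
  pos <- map$position_cM[idx]
  keep <- logical(nrow(ranking))
  for (i in seq_len(nrow(ranking))) {
    if (is.na(chrom[i])) {
      keep[i] <- TRUE
      next
    }
    prev <- which(keep & !is.na(chrom) & chrom == chrom[i])
    keep[i] <- !length(prev) || all(abs(pos[prev] - pos[i]) > min_cM)
  }
  out <- ranking[keep, ]
  out$rank <- seq_len(nrow(out))
  out
}

#' Build top-K or random marker subsets
#'
#' Top subsets are nested prefixes of the (typically pruned) ranking; random
#' subsets are uniform draws without replacement from the full locus list
#' and are also nested across sizes so the marker-requirement curve uses a
#' growing panel.
#'
#' @param ranking `locus_ranking` tibble.
#' @param sizes Integer vector of subset sizes.
#' @param random Draw random subsets instead of top-ranked prefixes.
#' @param seed Integer seed for random subsets.
#'
#' @return Named list (names = sizes) of locus-id character vectors.
#' @export
make_subsets <- function(ranking, sizes = c(25, 50, 75, 100, 125, 150,
                                            200, 250, 300),
                         random = FALSE, seed = 1L) {
  sizes <- sort(unique(as.integer(sizes)))
  if (any(sizes < 1)) abort("subset sizes must be >= 1")
  if (max(sizes) > nrow(ranking)) {
    abort(sprintf("largest size (%d) exceeds available loci (%d)",
                  max(sizes), nrow(ranking)))
  }
  pool <- if (random) {
    with_seed(seed, sample(ranking$locus, max(sizes)))
  } else {
    ranking$locus[seq_len(max(sizes))]
  }
  out <- lapply(sizes, function(s) pool[seq_len(s)])
  names(out) <- as.character(sizes)
  out
}

#' Top-K overlap between two rankings
#'
#' Number of loci shared by the top `k` of two rankings; the quantity behind
#' Venn-style comparisons of ranking methods.
#'
#' @param a,b `locus_ranking` tibbles.
#' @param k Depth of the comparison (default 100).
#'
#' @return Integer overlap in \[0, k\].
#' @export
ranking_overlap <- function(a, b, k = 100L) {
  k <- check_count(k, "k")
  length(intersect(a$locus[seq_len(min(k, nrow(a)))],
                   b$locus[seq_len(min(k, nrow(b)))]))
}
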