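# Neighbor-joining trees from D_A distances, with locus-bootstrap support.

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining (via \pkg{ape}); negative branch lengths,
#' which NJ can produce on non-additive matrices, are truncated to 0.
#'
#' @param d Symmetric distance matrix with population dimnames, or a
#'   `dist` object.
#'
#' @return An unrooted `phylo` tree.
#' @export
nj_tree <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!is.matrix(d) || nrow(d) != ncol(d)) {
    abort("`d` must be a square distance matrix")
  }
  if (max(abs(d - t(d))) > 1e-8) abort("distance matrix must be symmetric")
  if (nrow(d) < 3) abort("neighbor joining needs at least 3 populations")
  tr <- ape::nj(as.dist(d))
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Bootstrap consensus NJ tree from allele frequencies
#'
#' Resamples loci with replacement, recomputes Nei's D_A and the NJ tree per
#' replicate, and returns the majority-rule consensus with per-split support
#' as the percentage of replicates containing the split.
#'
#' @param freqs Wide biallelic frequency tibble (`locus` + population
#'   columns).
#' @param B Number of bootstrap replicates (the field convention is 1000;
#'   smaller values are useful for tests).
#' @param seed Integer seed.
#' @param keep_trees Keep the replicate trees in attribute `boot_trees`.
#'
#' @return A `phylo` consensus tree whose `node.label` holds percent
#'   bootstrap support.
#' @export
bootstrap_consensus <- function(freqs, B = 1000L, seed = 1L,
                                keep_trees = FALSE) {
  B <- check_count(B, "B")
  p <- freq_matrix(freqs)
  trees <- with_seed(seed, {
    lapply(seq_len(B), function(b) {
      idx <- sample.int(nrow(p), nrow(p), replace = TRUE)
      nj_tree(nei_da(freq_tibble(p[idx, , drop = FALSE])))
    })
  })
  class(trees) <- "multiPhylo"
  cons <- ape::consensus(trees, p = 0.5)
  counts <- ape::prop.clades(cons, trees, rooted = FALSE)
  counts[is.na(counts)] <- 0
  cons$node.label <- round(100 * counts / B, 1)
  if (keep_trees) attr(cons, "boot_trees") <- trees
  cons
}

#' Bootstrap support for one population split
#'
#' Fraction (percent) of bootstrap replicate trees containing the
#' bipartition separating `group` from the remaining populations. Useful for
#' checking a specific, e.g. planted, split.
#'
#' @param tree Consensus tree from [bootstrap_consensus()] built with
#'   `keep_trees = TRUE`.
#' @param group Character vector of population labels on one side of the
#'   split.
#'
#' @return Percent support in \[0, 100\].
#' @export
split_support <- function(tree, group) {
  trees <- attr(tree, "boot_trees")
  if (is.null(trees)) abort("tree lacks boot_trees; rerun with keep_trees = TRUE")
  tips <- tree$tip.label
  if (!all(group %in% tips)) abort("`group` contains unknown populations")
  hit <- vapply(trees, function(tr) {
    parts <- ape::prop.part(tr)
    labs <- attr(parts, "labels")
    any(vapply(parts, function(cl) {
      side <- labs[cl]
      setequal(side, group) || setequal(side, setdiff(tips, group))
    }, logical(1)))
  }, logical(1))
  100 * mean(hit)
}
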