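test_that("ranking sorts by score with deterministic tie-breaking", {
  div <- tibble::tibble(locus = c("L2", "L1"), delta = c(0.2, 0.5),
                        fst_global = c(0.1, 0.3),
                        fst_pairwise_mean = c(0.1, 0.3))
  rk <- rank_loci(div, "delta")
  expect_identical(rk$locus, c("L1", "L2"))
  expect_identical(rk$rank, 1:2)

  ties <- tibble::tibble(locus = c("Lb", "La", "Lc"), delta = c(0.4, 0.4, 0.4))
  expect_identical(rank_loci(ties, "delta")$locus, c("La", "Lb", "Lc"))

  # undefined scores rank last
  with_na <- tibble::tibble(locus = c("L1", "L2", "L3"),
                            delta = c(0.1, NA, 0.6))
  expect_identical(rank_loci(with_na, "delta")$locus, c("L3", "L1", "L2"))
  expect_error(rank_loci(div, "nope"))
})

test_that("ranking agrees with an independent sort oracle", {
  set.seed(51)
  div <- tibble::tibble(locus = sprintf("L%03d", sample(1:50)),
                        delta = runif(50))
  rk <- rank_loci(div, "delta")
  oracle <- div$locus[order(-div$delta, div$locus)]
  expect_identical(rk$locus, oracle)
})

test_that("upper-quartile classification follows the stated quantile rule", {
  scores <- 1:100
  flags <- classify_upper_quartile(scores)
  thr <- quantile(scores, 0.75, type = 7, names = FALSE)  # 75.25
  expect_identical(flags, scores >= thr)
  expect_equal(sum(flags), 25)

  expect_true(all(classify_upper_quartile(rep(3, 10))))
  expect_identical(classify_upper_quartile(c(0, 0, 0, 1)),
                   c(FALSE, FALSE, FALSE, TRUE))
  expect_error(classify_upper_quartile(c(1, 2, 3)), "at least 4")
})

test_that("linkage pruning keeps only loci farther apart than min_cM", {
  map <- tibble::tibble(locus = c("L1", "L2", "L3"),
                        chromosome = c("c1", "c1", "c2"),
                        position_cM = c(10, 10.5, 10))
  rk <- tibble::tibble(rank = 1:3, locus = c("L1", "L2", "L3"),
                       score = c(3, 2, 1), method = "delta")
  pruned <- prune_linked(rk, map, min_cM = 1)
  expect_identical(pruned$locus, c("L1", "L3"))  # co-located: better kept
  # loci on different chromosomes are unlinked by definition
  map2 <- dplyr::mutate(map, chromosome = c("c1", "c2", "c3"))
  expect_equal(nrow(prune_linked(rk, map2, 1)), 3)
  # unmapped loci are kept with a warning
  expect_warning(pr <- prune_linked(rk, map[-1, ], 1), "unlinked")
  expect_true("L1" %in% pr$locus)
})

test_that("pruned rankings never contain a linked pair (exhaustive check)", {
  map <- generate_panel_map(100, 5, 50, seed = 61)
  set.seed(62)
  rk <- tibble::tibble(rank = 1:100, locus = sample(map$locus),
                       score = sort(runif(100), decreasing = TRUE),
                       method = "delta")
  pruned <- prune_linked(rk, map, min_cM = 1)
  pos <- map$position_cM[match(pruned$locus, map$locus)]
  chr <- map$chromosome[match(pruned$locus, map$locus)]
  for (i in seq_len(nrow(pruned) - 1)) {
    for (j in (i + 1):nrow(pruned)) {
      if (chr[i] == chr[j]) expect_gt(abs(pos[i] - pos[j]), 1)
    }
  }
  # greedy maximality: every dropped locus conflicts with a kept one
  dropped <- setdiff(rk$locus, pruned$locus)
  for (d in dropped) {
    dp <- map$position_cM[map$locus == d]
    dc <- map$chromosome[map$locus == d]
    expect_true(any(chr == dc & abs(pos - dp) <= 1))
  }
})

test_that("subset construction nests top-K prefixes and reproduces random draws", {
  rk <- tibble::tibble(rank = 1:300, locus = sprintf("L%03d", 1:300),
                       score = rev(seq_len(300)) / 300, method = "delta")
  subs <- make_subsets(rk, sizes = c(25, 50))
  expect_true(all(subs[["25"]] %in% subs[["50"]]))
  expect_identical(subs[["25"]], rk$locus[1:25])

  r1 <- make_subsets(rk, sizes = c(100), random = TRUE, seed = 3)
  r2 <- make_subsets(rk, sizes = c(100), random = TRUE, seed = 3)
  expect_identical(r1, r2)
  expect_equal(length(unique(r1[["100"]])), 100)
  expect_error(make_subsets(rk, sizes = 400), "exceeds")
})

test_that("top-k overlap is symmetric, bounded and reflexive", {
  set.seed(71)
  a <- tibble::tibble(locus = sample(sprintf("L%03d", 1:200)))
  b <- tibble::tibble(locus = sample(sprintf("L%03d", 1:200)))
  expect_equal(ranking_overlap(a, a, 100), 100)
  expect_equal(ranking_overlap(a, b, 100), ranking_overlap(b, a, 100))
  expect_lte(ranking_overlap(a, b, 100), 100)
})

test_that("delta and pairwise-F_ST rankings overlap strongly on structured data", {
  sim <- generate_population_frequencies(15, 600, fst = 0.05,
                                         outlier_frac = 0.05,
                                         outlier_multiplier = 8, seed = 81)
  div <- locus_divergence(sim$freqs)
  ov <- ranking_overlap(rank_loci(div, "delta"),
                        rank_loci(div, "pairwise_fst"), 100)
  expect_gte(ov, 50)
})
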