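test_that("panel maps place loci on chromosomes deterministically", {
  map <- generate_panel_map(10, n_chromosomes = 1, chrom_length_cM = 100,
                            seed = 1)
  expect_equal(nrow(map), 10)
  expect_length(unique(map$chromosome), 1)
  expect_true(all(map$position_cM >= 0 & map$position_cM <= 100))
  expect_identical(map,
                   generate_panel_map(10, 1, 100, seed = 1))
  big <- generate_panel_map(2880, 29, 120, seed = 7)
  expect_equal(length(unique(big$locus)), 2880)
  expect_false(is.unsorted(big$position_cM[big$chromosome == "chr01"]))
  expect_error(generate_panel_map(0, 1, 100), "n_loci")
})

test_that("population frequencies follow the Balding-Nichols F-model", {
  # zero-divergence limit: populations collapse onto the ancestral frequency
  tiny <- generate_population_frequencies(5, 1000, fst = 1e-6, seed = 2)
  dev <- abs(as.matrix(tiny$freqs[-1]) - tiny$truth$ancestral)
  expect_lt(max(dev), 0.01)

  # estimator calibration against the generating F
  sim <- generate_population_frequencies(20, 2000, fst = 0.05, seed = 3)
  g <- fst_global(sim$freqs, n_ind = 50)
  expect_lt(abs(attr(g, "mean") - 0.05), 0.01)

  # convergence of realized global F_ST at large locus counts
  sim5k <- generate_population_frequencies(20, 5000, fst = 0.05, seed = 4)
  g5k <- fst_global(sim5k$freqs, n_ind = 50)
  expect_lt(abs(attr(g5k, "mean") - 0.05), 0.005)

  # outlier loci stochastically dominate the neutral F_ST distribution
  pl <- generate_population_frequencies(20, 2000, fst = 0.05,
                                        outlier_frac = 0.05,
                                        outlier_multiplier = 8, seed = 5)
  expect_equal(sum(pl$truth$outlier), 100)  # exact planted fraction
  fst <- fst_global(pl$freqs, n_ind = 50)$fst
  out <- pl$truth$outlier
  expect_gt(median(fst[out], na.rm = TRUE),
            median(fst[!out], na.rm = TRUE))
  expect_lt(wilcox.test(fst[out], fst[!out],
                        alternative = "greater")$p.value, 0.01)

  # determinism and validation
  expect_identical(generate_population_frequencies(4, 50, 0.1, seed = 6),
                   generate_population_frequencies(4, 50, 0.1, seed = 6))
  expect_error(generate_population_frequencies(4, 50, fst = 0.3,
                                               outlier_multiplier = 4),
               "below 1")
})

test_that("cluster references keep strict AA < AB < BB ordering", {
  exact <- generate_cluster_reference(20, jitter_sd = 0, seed = 1)
  expect_true(all(exact$theta_AA == 0.05 & exact$theta_AB == 0.5 &
                    exact$theta_BB == 0.95))
  ref <- generate_cluster_reference(500, centers = c(0.05, 0.5, 0.95),
                                    jitter_sd = 0.02, seed = 2)
  expect_true(all(ref$theta_AA < ref$theta_AB & ref$theta_AB < ref$theta_BB))
  expect_identical(ref, generate_cluster_reference(500, jitter_sd = 0.02,
                                                   seed = 2))
  expect_error(generate_cluster_reference(5, centers = c(0.5, 0.4, 0.9)),
               "increasing")
})

test_that("pool replicates invert exactly at zero noise", {
  sim <- generate_population_frequencies(5, 200, fst = 0.05, seed = 3)
  ref <- generate_cluster_reference(200, jitter_sd = 0.02, seed = 4)
  reps <- generate_pool_replicates(sim$freqs, ref, n_replicates = 3,
                                   theta_noise_sd = 0, seed = 5)
  est <- pool_frequencies(reps, ref)
  p0 <- as.matrix(sim$freqs[-1])
  p1 <- as.matrix(est[match(sim$freqs$locus, est$locus), colnames(sim$freqs)][-1])
  expect_lt(max(abs(p0 - p1)), 1e-12)

  # fixed locus: theta collapses onto the AA cluster mean
  fixed <- tibble::tibble(locus = ref$locus[1:3], popA = 0)
  th <- generate_pool_replicates(fixed, ref, n_replicates = 2,
                                 theta_noise_sd = 0, seed = 6)
  expect_equal(th$theta, rep(ref$theta_AA[1:3], each = 2), tolerance = 1e-12)
})

test_that("replicate noise matches the configured SD on average", {
  sim <- generate_population_frequencies(2, 2000, fst = 0.05, seed = 7)
  ref <- generate_cluster_reference(2000, jitter_sd = 0.02, seed = 8)
  reps <- generate_pool_replicates(sim$freqs, ref, n_replicates = 4,
                                   theta_noise_sd = 0.01, seed = 9)
  sds <- reps %>%
    dplyr::group_by(population, locus) %>%
    dplyr::summarise(s = sd(theta), .groups = "drop")
  c4 <- sqrt(2 / 3) * gamma(2) / gamma(1.5)  # E[sample SD] / sigma at n = 4
  expect_lt(abs(mean(sds$s) - 0.01 * c4) / (0.01 * c4), 0.2)
})

test_that("multiallelic frequencies are simplex-valued and F-controlled", {
  tab <- generate_multiallelic_loci(6, alleles_per_locus = rep(4, 10),
                                    fst = 0.1, seed = 10)
  sums <- tab %>%
    dplyr::group_by(locus) %>%
    dplyr::summarise(dplyr::across(dplyr::starts_with("pop"), sum))
  expect_true(all(abs(as.matrix(sums[-1]) - 1) < 1e-9))

  # biallelic case reduces to a standard frequency table
  bi <- generate_multiallelic_loci(4, alleles_per_locus = rep(2, 5),
                                   fst = 0.1, seed = 11)
  bi_sums <- bi %>%
    dplyr::group_by(locus) %>%
    dplyr::summarise(dplyr::across(dplyr::starts_with("pop"), sum))
  expect_true(all(abs(as.matrix(bi_sums[-1]) - 1) < 1e-9))

  # near-zero divergence: populations share the ancestral simplex point
  flat <- generate_multiallelic_loci(5, alleles_per_locus = rep(6, 20),
                                     fst = 1e-6, seed = 12)
  m <- as.matrix(flat[grep("^pop", names(flat))])
  tv <- max(vapply(seq_len(nrow(m)), function(i) {
    (max(m[i, ]) - min(m[i, ])) / 2
  }, numeric(1)))
  expect_lt(tv, 0.02)
  expect_error(generate_multiallelic_loci(3, rep(2, 5), fst = 1.2), "fst")

  # STR-style sizing: 18 loci with sum(k - 1) = 219 independent alleles
  k_str <- c(rep(13, 15), rep(14, 3))
  expect_equal(independent_alleles(k_str), 219L)
})
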