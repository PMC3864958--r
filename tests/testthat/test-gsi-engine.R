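test_that("simulated genotypes follow HWE at each locus", {
  fixed <- tibble::tibble(locus = c("L1", "L2"), popA = c(1, 0))
  g <- simulate_genotypes(fixed, 20, role = "baseline", seed = 1)
  expect_true(all(g$geno[, "L1"] == 2))
  expect_true(all(g$geno[, "L2"] == 0))

  half <- tibble::tibble(locus = "L1", popA = 0.5)
  gh <- simulate_genotypes(half, 10000, role = "mixture", seed = 2)
  props <- tabulate(gh$geno[, 1] + 1, 3) / 10000
  expect_true(all(abs(props - c(0.25, 0.5, 0.25)) < 0.02))

  expect_identical(simulate_genotypes(half, 100, seed = 3),
                   simulate_genotypes(half, 100, seed = 3))
})

test_that("Rannala-Mountain probabilities match the beta-binomial closed form", {
  set.seed(4)
  for (i in 1:25) {
    n <- sample(0:300, 1)
    x_b <- if (n == 0) 0 else sample(0:n, 1)
    probs <- exp(poolgsi:::rm_log_geno_probs(x_b, n))
    oracle <- vapply(0:2, function(g) oracle_rm_prob(g, x_b, n), numeric(1))
    expect_equal(as.vector(probs), oracle, tolerance = 1e-12)
    expect_equal(sum(probs), 1, tolerance = 1e-12)
  }
  # empty baseline: the prior alone gives (0.375, 0.25, 0.375)
  expect_equal(as.vector(exp(poolgsi:::rm_log_geno_probs(0, 0))),
               c(0.375, 0.25, 0.375))
  # all-A baseline strongly penalizes, never zeroes, a BB genotype
  p_bb <- exp(poolgsi:::rm_log_geno_probs(0, 200))[3]
  expect_equal(p_bb, (0.5 * 1.5) / (201 * 202), tolerance = 1e-12)
})

test_that("the genotype likelihood sums logs over loci against the baseline", {
  freqs <- tibble::tibble(locus = c("L1", "L2"), pa = c(0.2, 0.8),
                          pb = c(0.9, 0.1))
  base <- simulate_genotypes(freqs, 50, role = "baseline", seed = 5)
  bl <- baseline_counts(base)
  mix <- simulate_genotypes(freqs, 4, role = "mixture", seed = 6)
  ll <- genotype_log_likelihood(mix, bl)
  # independent per-individual recomputation
  for (i in seq_len(nrow(mix$geno))) {
    for (s in rownames(bl$b_count)) {
      acc <- 0
      for (l in colnames(mix$geno)) {
        acc <- acc + log(oracle_rm_prob(mix$geno[i, l], bl$b_count[s, l],
                                        bl$n_copies[s, l]))
      }
      expect_equal(ll[i, s], acc, tolerance = 1e-12)
    }
  }
})

test_that("EM recovers mixture proportions and increases the likelihood", {
  sim <- generate_population_frequencies(3, 100, fst = 0.1, seed = 21)
  bl <- baseline_counts(simulate_genotypes(sim$freqs, 100,
                                           role = "baseline", seed = 22))
  mix <- simulate_genotypes(sim$freqs,
                            c(pop01 = 250, pop02 = 150, pop03 = 100),
                            role = "mixture", seed = 23)
  fit <- em_mixture(mix, bl)
  expect_lte(max(abs(fit$proportions$proportion - c(0.5, 0.3, 0.2))), 0.05)
  expect_true(all(diff(fit$loglik_trace) >= -1e-8))
  expect_equal(sum(fit$proportions$proportion), 1, tolerance = 1e-9)
  expect_s3_class(tidy(fit), "tbl_df")
  expect_true(glance(fit)$converged)
})

test_that("EM splits indistinguishable stocks but recovers their joint share", {
  one <- generate_population_frequencies(1, 120, fst = 0.2, seed = 24)$freqs
  freqs <- dplyr::mutate(one, pop02 = .data$pop01)  # identical twin stock
  other <- generate_population_frequencies(1, 120, fst = 0.2, seed = 25)$freqs
  freqs$pop03 <- other$pop01
  bl <- baseline_counts(simulate_genotypes(freqs, 200, role = "baseline",
                                           seed = 26))
  mix <- simulate_genotypes(freqs, c(pop01 = 150, pop02 = 150, pop03 = 200),
                            role = "mixture", seed = 27)
  fit <- em_mixture(mix, bl)
  th <- setNames(fit$proportions$proportion, fit$proportions$population)
  expect_lte(abs((th["pop01"] + th["pop02"]) - 0.6), 0.03)
})

test_that("assignment posteriors are proper and respect strong signals", {
  # private fixed alleles make origin certain
  freqs <- tibble::tibble(locus = sprintf("L%02d", 1:10),
                          pa = rep(0.01, 10), pb = rep(0.99, 10))
  bl <- baseline_counts(simulate_genotypes(freqs, 100, role = "baseline",
                                           seed = 31))
  mix <- simulate_genotypes(freqs, c(pa = 20, pb = 0), role = "mixture",
                            seed = 32)
  res <- gsi_assign(mix, bl, prior = "uniform")
  expect_true(all(abs(rowSums(res$posterior) - 1) < 1e-9))
  expect_gt(mean(res$posterior[, "pa"]), 0.999)

  # identical populations, uniform prior: posteriors are exactly split
  freqs2 <- tibble::tibble(locus = sprintf("L%02d", 1:5), x = runif(5),
                           y = NA)
  freqs2$y <- freqs2$x
  bl2 <- poolgsi::baseline_counts(
    simulate_genotypes(freqs2[c("locus", "x")], 50, role = "baseline",
                       seed = 33))
  # duplicate the single baseline population under two names
  bl2$b_count <- rbind(x = bl2$b_count["x", ], y = bl2$b_count["x", ])
  bl2$n_copies <- rbind(x = bl2$n_copies["x", ], y = bl2$n_copies["x", ])
  mix2 <- simulate_genotypes(freqs2[c("locus", "x")], 10, role = "mixture",
                             seed = 34)
  expect_warning(res2 <- gsi_assign(mix2, bl2, prior = "uniform"), "tied")
  expect_true(all(abs(res2$posterior - 0.5) < 1e-12))
})

test_that("accuracy evaluation aggregates per-population results exactly", {
  sim <- generate_population_frequencies(4, 60, fst = 0.15, seed = 41)
  bl <- baseline_counts(simulate_genotypes(sim$freqs, 100,
                                           role = "baseline", seed = 42))
  mix <- simulate_genotypes(sim$freqs, 50, role = "mixture", seed = 43)
  res <- gsi_assign(mix, bl)
  acc <- evaluate_accuracy(res)
  expect_equal(acc$overall_pct,
               with(acc$per_population, sum(n * pct_correct) / sum(n)))
  expect_true(all(acc$per_population$pct_correct >= 0 &
                    acc$per_population$pct_correct <= 100))
})

test_that("assignment among indistinguishable stocks is at chance level", {
  # 23 identical populations: accuracy ~ 1/23
  base_p <- runif(20, 0.2, 0.8)
  freqs <- dplyr::bind_cols(
    tibble::tibble(locus = sprintf("L%02d", 1:20)),
    tibble::as_tibble(matrix(rep(base_p, 23), ncol = 23,
                             dimnames = list(NULL, sprintf("pop%02d", 1:23)))))
  bl <- baseline_counts(simulate_genotypes(freqs, 30, role = "baseline",
                                           seed = 44))
  mix <- simulate_genotypes(freqs, 100, role = "mixture", seed = 45)
  acc <- evaluate_accuracy(gsi_assign(mix, bl, prior = "uniform"))
  expect_lt(abs(acc$overall_pct - 100 / 23), 2)
})

test_that("independent-allele counting is sum(k - 1)", {
  expect_equal(independent_alleles(rep(2, 100)), 100L)
  expect_equal(independent_alleles(c(rep(13, 15), rep(14, 3))), 219L)
  expect_equal(independent_alleles(integer(0)), 0L)
  expect_error(independent_alleles(c(2, 1)), ">= 2")
})

test_that("the exponential fit recovers noiseless parameters exactly", {
  x <- c(25, 50, 75, 100, 150, 200, 300)
  a0 <- log(100); b0 <- -50
  curve <- tibble::tibble(independent_alleles = x,
                          overall_pct = exp(a0 + b0 / x))
  fit <- fit_required_markers(curve)
  expect_equal(fit$a, a0, tolerance = 1e-9)
  expect_equal(fit$b, b0, tolerance = 1e-9)
  req95 <- fit$required$required_markers[fit$required$target_pct == 95]
  expect_equal(req95, ceiling(-50 / (log(95) - log(100))))
  expect_equal(req95, 975)

  # saturated flat curve: everything attained at the smallest panel
  flat <- tibble::tibble(independent_alleles = x, overall_pct = 100)
  ffit <- fit_required_markers(flat)
  expect_true(all(ffit$required$attainable))
  expect_true(all(ffit$required$required_markers == 25))

  # target above the fitted asymptote is unattainable
  low <- tibble::tibble(independent_alleles = x,
                        overall_pct = exp(log(90) - 30 / x))
  lfit <- fit_required_markers(low, targets = c(80, 95))
  expect_true(lfit$required$attainable[lfit$required$target_pct == 80])
  expect_false(lfit$required$attainable[lfit$required$target_pct == 95])
  expect_true(is.na(lfit$required$required_markers[2]))
})

test_that("accuracy curves reject degenerate panels and track information", {
  sim <- generate_population_frequencies(6, 150, fst = 0.08, seed = 51)
  div <- locus_divergence(sim$freqs)
  rk <- rank_loci(div, "delta")
  expect_error(accuracy_curve(sim$freqs, rk, sizes = 0), ">= 1")
  expect_error(accuracy_curve(sim$freqs, rk, sizes = 1000), "exceeds")
  cv <- accuracy_curve(sim$freqs, rk, sizes = c(10, 40, 120),
                       n_baseline = 50, n_mixture = 50, seed = 52)
  expect_true(all(diff(cv$overall_pct) > -1))  # non-decreasing up to noise
  expect_true(all(cv$overall_pct >= 0 & cv$overall_pct <= 100))
  expect_identical(cv$independent_alleles, cv$size)
})

test_that("self-assignment is at least as accurate as mixture assignment", {
  sim <- generate_population_frequencies(8, 120, fst = 0.08, seed = 61)
  base <- simulate_genotypes(sim$freqs, 80, role = "baseline", seed = 62)
  bl <- baseline_counts(base)
  mix <- simulate_genotypes(sim$freqs, 80, role = "mixture", seed = 63)
  acc_self <- evaluate_accuracy(gsi_assign(base, bl, prior = "uniform"))
  acc_mix <- evaluate_accuracy(gsi_assign(mix, bl, prior = "uniform"))
  expect_gte(acc_self$overall_pct, acc_mix$overall_pct - 1e-9)
})

test_that("mixture composition has only minor influence on accuracy", {
  sim <- generate_population_frequencies(5, 200, fst = 0.1, seed = 71)
  div <- locus_divergence(sim$freqs)
  rk <- rank_loci(div, "pairwise_fst")
  even <- accuracy_curve(sim$freqs, rk, sizes = 100, n_baseline = 100,
                         n_mixture = 200, seed = 72)
  skew <- accuracy_curve(sim$freqs, rk, sizes = 100, n_baseline = 100,
                         n_mixture = 200,
                         mixture_props = c(pop01 = 0.8, pop02 = 0.05,
                                           pop03 = 0.05, pop04 = 0.05,
                                           pop05 = 0.05),
                         seed = 72)
  expect_lt(abs(even$overall_pct - skew$overall_pct), 5)
})
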