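# Genetic stock identification: baseline/mixture genotype simulation,
# Rannala-Mountain genotype likelihoods, EM mixture-composition estimation
# and individual assignment.

#' Simulate multilocus genotypes from population allele frequencies
#'
#' Draws individuals' B-allele counts per locus as Binomial(2, p) under
#' Hardy-Weinberg and linkage equilibrium, the standard assumption for
#' building GSI baselines and mixtures from frequency estimates.
#'
#' @param freqs Wide frequency tibble (`locus` + population columns).
#' @param n_per_pop Individuals to simulate per population; scalar or named
#'   per-population vector.
#' @param loci Optional character vector restricting (and ordering) the loci
#'   used, e.g. one subset from [make_subsets()].
#' @param role Label stored on the result: `"baseline"` or `"mixture"`.
#' @param seed Integer seed.
#'
#' @return An object of class `genotypes`: list with `geno` (integer matrix,
#'   individuals x loci, entries 0/1/2 B-allele counts), `origin` (true
#'   population per individual), `role`.
#' @export
simulate_genotypes <- function(freqs, n_per_pop, loci = NULL,
                               role = c("baseline", "mixture"), seed = 1L) {
  role <- match.arg(role)
  p <- freq_matrix(freqs)
  if (!is.null(loci)) {
    miss <- setdiff(loci, rownames(p))
    if (length(miss)) abort(paste0("loci absent from freqs: ", toString(miss[1:min(3, length(miss))])))
    p <- p[loci, , drop = FALSE]
  }
  pops <- colnames(p)
  n_per_pop <- if (is.null(names(n_per_pop))) {
    setNames(rep_len(n_per_pop, length(pops)), pops)
  } else n_per_pop[pops]
  if (any(is.na(n_per_pop)) || any(n_per_pop < 0)) {
    abort("`n_per_pop` must cover all populations with counts >= 0")
  }
  with_seed(seed, {
    mats <- lapply(pops, function(pop) {
      n <- n_per_pop[[pop]]
      if (n == 0) return(NULL)
      matrix(rbinom(n * nrow(p), 2L, rep(p[, pop], each = n)),
             nrow = n, ncol = nrow(p))
    })
  })
  geno <- do.call(rbind, mats)
  origin <- rep(pops, times = n_per_pop)
  colnames(geno) <- rownames(p)
  rownames(geno) <- sprintf("%s_%s_%04d", role, origin,
                            unlist(lapply(n_per_pop, seq_len), use.names = FALSE))
  structure(list(geno = geno, origin = origin, role = role),
            class = "genotypes")
}

#' @export
print.genotypes <- function(x, ...) {
  cat(sprintf("%s genotypes: %d individuals x %d loci from %d populations\n",
              x$role, nrow(x$geno), ncol(x$geno),
              length(unique(x$origin))))
  invisible(x)
}

#' @describeIn simulate_genotypes Long-tibble view of a genotype object
#'   (`individual`, `origin`, `locus`, `genotype`).
#' @param x A `genotypes` object.
#' @param ... Unused.
#' @export
tidy.genotypes <- function(x, ...) {
  tibble::tibble(
    individual = rep(rownames(x$geno), times = ncol(x$geno)),
    origin = rep(x$origin, times = ncol(x$geno)),
    locus = rep(colnames(x$geno), each = nrow(x$geno)),
    genotype = as.integer(x$geno)
  )
}

#' Tally baseline allele counts per population
#'
#' Reduces a baseline genotype sample to per-population B-allele counts and
#' gene-copy totals, the sufficient statistics of the Rannala-Mountain
#' genotype-frequency estimate.
#'
#' @param baseline A `genotypes` object (typically `role = "baseline"`).
#'
#' @return Object of class `baseline_counts`: list with `b_count` and
#'   `n_copies` (population x locus matrices).
#' @export
baseline_counts <- function(baseline) {
  stopifnot(inherits(baseline, "genotypes"))
  pops <- sort(unique(baseline$origin))
  b <- t(vapply(pops, function(pop) {
    colSums(baseline$geno[baseline$origin == pop, , drop = FALSE])
  }, numeric(ncol(baseline$geno))))
  n <- t(vapply(pops, function(pop) {
    rep(2 * sum(baseline$origin == pop), ncol(baseline$geno))
  }, numeric(ncol(baseline$geno))))
  dimnames(b) <- dimnames(n) <- list(pops, colnames(baseline$geno))
  structure(list(b_count = b, n_copies = n), class = "baseline_counts")
}

# Rannala-Mountain per-locus log genotype probabilities for one population:
# returns 3-row matrix (genotype 0/1/2 B alleles) x loci.  With baseline
# counts (x_A, x_B) of n gene copies and a Dirichlet(1/2, 1/2) prior,
#   P(AA) = (x_A + 1/2)(x_A + 3/2) / ((n + 1)(n + 2))
#   P(AB) = 2 (x_A + 1/2)(x_B + 1/2) / ((n + 1)(n + 2))
#   P(BB) = (x_B + 1/2)(x_B + 3/2) / ((n + 1)(n + 2))
rm_log_geno_probs <- function(x_b, n) {
  x_a <- n - x_b
  den <- (n + 1) * (n + 2)
  rbind(
    log((x_a + 0.5) * (x_a + 1.5) / den),
    log(2 * (x_a + 0.5) * (x_b + 0.5) / den),
    log((x_b + 0.5) * (x_b + 1.5) / den)
  )
}

#' Rannala-Mountain log-likelihood of genotypes against a baseline
#'
#' Per-individual, per-population log-likelihoods under the
#' Rannala-Mountain posterior-predictive genotype frequencies: each
#' population's allele frequency carries a Dirichlet(1/2, 1/2) prior updated
#' by the baseline allele counts, giving Polya-urn genotype probabilities
#' that never vanish, and loci combine by summation of logs (linkage
#' equilibrium).
#'
#' @param genotypes A `genotypes` object (the mixture sample).
#' @param baseline A `baseline_counts` object covering the same loci.
#'
#' @return Numeric matrix, individuals x populations, of log-likelihoods.
#' @export
genotype_log_likelihood <- function(genotypes, baseline) {
  stopifnot(inherits(genotypes, "genotypes"),
            inherits(baseline, "baseline_counts"))
  loci <- colnames(genotypes$geno)
  if (!all(loci %in% colnames(baseline$b_count))) {
    abort("baseline does not cover all mixture loci")
  }
  pops <- rownames(baseline$b_count)
  g <- genotypes$geno
  ind0 <- (g == 0L) * 1
  ind1 <- (g == 1L) * 1
  ind2 <- (g == 2L) * 1
  ll <- matrix(0, nrow(g), length(pops), dimnames = list(rownames(g), pops))
  for (s in seq_along(pops)) {
    lp <- rm_log_geno_probs(baseline$b_count[pops[s], loci],
                            baseline$n_copies[pops[s], loci])
    ll[, s] <- ind0 %*% lp[1, ] + ind1 %*% lp[2, ] + ind2 %*% lp[3, ]
  }
  ll
}

#' EM estimate of mixture stock composition
#'
#' Maximises the mixture likelihood `L(theta) = prod_i sum_s theta_s
#' P(g_i | s)` over the stock-proportion simplex by
#' expectation-maximisation: posterior memberships in the E-step, their
#' means in the M-step. The log-likelihood is non-decreasing across
#' iterations; iteration stops when its change falls below `tol`.
#'
#' @param mixture A `genotypes` object (the mixed sample).
#' @param baseline A `baseline_counts` object.
#' @param tol Convergence tolerance on the log-likelihood change
#'   (default 1e-6).
#' @param max_iter Maximum EM iterations (default 1000).
#'
#' @return Object of class `gsi_mixture`: `proportions` (tibble
#'   `population`, `proportion`), `loglik_trace`, `converged`, `n_iter`,
#'   plus the membership matrix and inputs needed by [gsi_assign()].
#' @export
em_mixture <- function(mixture, baseline, tol = 1e-6, max_iter = 1000L) {
  ll <- genotype_log_likelihood(mixture, baseline)
  S <- ncol(ll)
  theta <- rep(1 / S, S)
  trace <- numeric(0)
  prev <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    lw <- sweep(ll, 2, log(theta), `+`)
    m <- apply(lw, 1, max)
    w <- exp(lw - m)
    rs <- rowSums(w)
    loglik <- sum(log(rs) + m)
    trace <- c(trace, loglik)
    w <- w / rs
    theta <- colMeans(w)
    if (is.finite(prev) && abs(loglik - prev) < tol) {
      converged <- TRUE
      break
    }
    prev <- loglik
  }
  if (!converged) warn(sprintf("EM did not converge in %d iterations", max_iter))
  structure(
    list(
      proportions = tibble::tibble(population = colnames(ll),
                                   proportion = theta),
      loglik_trace = trace,
      converged = converged,
      n_iter = length(trace),
      membership = w,
      loglik_matrix = ll,
      origin = mixture$origin
    ),
    class = "gsi_mixture"
  )
}

#' @export
print.gsi_mixture <- function(x, ...) {
  cat(sprintf("GSI mixture analysis: %d individuals, %d baseline stocks, %s in %d EM iterations\n",
              nrow(x$membership), nrow(x$proportions),
              if (x$converged) "converged" else "not converged", x$n_iter))
  print(dplyr::arrange(x$proportions, dplyr::desc(.data$proportion)), n = 5)
  invisible(x)
}

#' @describeIn em_mixture Tidy the estimated stock proportions.
#' @param x A `gsi_mixture` object.
#' @param ... Unused.
#' @export
tidy.gsi_mixture <- function(x, ...) x$proportions

#' @describeIn em_mixture One-row model summary (loglik, iterations,
#'   convergence).
#' @export
glance.gsi_mixture <- function(x, ...) {
  tibble::tibble(
    logLik = x$loglik_trace[length(x$loglik_trace)],
    n_iter = x$n_iter,
    converged = x$converged,
    n_individuals = nrow(x$membership),
    n_stocks = nrow(x$proportions)
  )
}

#' Assign mixture individuals to baseline populations
#'
#' Posterior probability of each baseline stock for each individual,
#' `posterior(s | g) proportional to prior_s * P(g | s)`, with the prior
#' either the EM-estimated mixture proportions (the mixed-stock analysis
#' convention) or uniform (plain Rannala-Mountain assignment). Every
#' individual is assigned to its argmax stock regardless of posterior
#' confidence; ties break by population order with a warning.
#'
#' @param mixture A `genotypes` object.
#' @param baseline A `baseline_counts` object.
#' @param prior `"mixture"` (default; runs [em_mixture()] internally unless
#'   `fit` is supplied) or `"uniform"`.
#' @param fit Optional pre-computed `gsi_mixture` fit to reuse.
#'
#' @return Object of class `gsi_assignment`: `assignments` (tibble
#'   `individual`, `true_pop`, `assigned_pop`, `posterior`, `correct`),
#'   `posterior` (matrix individuals x populations), `prior`.
#' @export
gsi_assign <- function(mixture, baseline, prior = c("mixture", "uniform"),
                       fit = NULL) {
  prior <- match.arg(prior)
  if (prior == "mixture") {
    if (is.null(fit)) fit <- em_mixture(mixture, baseline)
    ll <- fit$loglik_matrix
    prior_vec <- fit$proportions$proportion
  } else {
    ll <- genotype_log_likelihood(mixture, baseline)
    prior_vec <- rep(1 / ncol(ll), ncol(ll))
  }
  lw <- sweep(ll, 2, log(pmax(prior_vec, 1e-300)), `+`)
  m <- apply(lw, 1, max)
  w <- exp(lw - m)
  post <- w / rowSums(w)
  n_max <- rowSums(post == apply(post, 1, max))
  if (any(n_max > 1)) {
    warn(sprintf("%d individuals had tied posteriors; assigned to the first population in order",
                 sum(n_max > 1)))
  }
  assigned <- colnames(post)[max.col(post, ties.method = "first")]
  structure(
    list(
      assignments = tibble::tibble(
        individual = rownames(post),
        true_pop = mixture$origin,
        assigned_pop = assigned,
        posterior = post[cbind(seq_len(nrow(post)),
                               match(assigned, colnames(post)))],
        correct = assigned == mixture$origin
      ),
      posterior = post,
      prior = prior
    ),
    class = "gsi_assignment"
  )
}

#' @export
print.gsi_assignment <- function(x, ...) {
  cat(sprintf("GSI assignment (%s prior): %d individuals, %.1f%% correct\n",
              x$prior, nrow(x$assignments),
              100 * mean(x$assignments$correct)))
  invisible(x)
}

#' @describeIn gsi_assign Tidy per-individual assignment records.
#' @param x A `gsi_assignment` object.
#' @param ... Unused.
#' @export
tidy.gsi_assignment <- function(x, ...) x$assignments

#' Assignment accuracy, overall and per population
#'
#' @param result A `gsi_assignment` object with true-origin labels.
#'
#' @return List with `overall_pct` (percent correctly assigned) and
#'   `per_population` (tibble `population`, `n`, `pct_correct`).
#' @export
evaluate_accuracy <- function(result) {
  stopifnot(inherits(result, "gsi_assignment"))
  a <- result$assignments
  per_pop <- a %>%
    dplyr::group_by(population = .data$true_pop) %>%
    dplyr::summarise(n = dplyr::n(),
                     pct_correct = 100 * mean(.data$correct),
                     .groups = "drop")
  list(overall_pct = 100 * mean(a$correct), per_population = per_pop)
}

#' Number of independent alleles in a marker panel
#'
#' `sum(k_l - 1)` over loci with `k_l` alleles; each biallelic SNP
#' contributes one independent allele, so SNP and multiallelic (STR) panels
#' become comparable on one information axis.
#'
#' @param alleles_per_locus Integer vector of allele counts per locus
#'   (each >= 2); may be empty.
#'
#' @return Integer count.
#' @export
independent_alleles <- function(alleles_per_locus) {
  if (length(alleles_per_locus) == 0) return(0L)
  if (any(alleles_per_locus < 2)) abort("each locus must have >= 2 alleles")
  as.integer(sum(alleles_per_locus - 1))
}
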