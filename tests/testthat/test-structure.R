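test_that("PCA separates two diverged populations on PC1", {
  sim <- simulate_panel(sim_config(n_populations = 2, samples_per_population = 50,
                                   n_snps = 2000, drift_f = 0.3, seed = 21))
  res <- pca_panel(sim$panel)
  pc1 <- res$scores[, 1]
  a <- pc1[1:50]; b <- pc1[51:100]
  expect_true(max(a) < min(b) || max(b) < min(a))
  expect_true(all(diff(res$explained) <= 1e-9))   # non-increasing
  expect_lte(sum(res$explained), 1 + 1e-9)
})

test_that("PCA rejects missing data and all-monomorphic panels", {
  p <- hwe_panel(5, 10, 0.5, seed = 1)
  p$dosages[1, 1] <- NA
  expect_error(pca_panel(p), "impute_missing")
  mono <- hwe_panel(5, 10, 0.5, seed = 1)
  mono$dosages[] <- 2L
  expect_error(pca_panel(mono), "no polymorphic SNPs")
})

test_that("duplicating every individual leaves PC directions unchanged", {
  p <- hwe_panel(20, 100, 0.4, seed = 22)
  dup <- genotype_panel(c(p$samples, paste0(p$samples, "_b")),
                        p$snps, rbind(p$dosages, p$dosages))
  r1 <- pca_panel(p, n_components = 3)
  r2 <- pca_panel(dup, n_components = 3)
  # scores of the duplicated panel come in two identical halves
  expect_equal(r2$scores[1:20, ], r2$scores[21:40, ], ignore_attr = TRUE)
  # directions match up to scale: correlation of loadings ~ +/-1
  for (c in 1:2) {
    expect_gt(abs(cor(r1$loadings[, c], r2$loadings[, c])), 0.999)
  }
})

test_that("population mean scores are exact member means inside the convex hull", {
  p <- hwe_panel(6, 50, 0.4, seed = 23)
  pm <- population_map(p$samples, rep(c("P1", "P2"), each = 3), "c")
  res <- population_mean_scores(pca_panel(p, n_components = 2), pm)
  for (pop in c("P1", "P2")) {
    rows <- which(pm$population == pop)
    for (c in 1:2) {
      sc <- res$scores[rows, c]
      expect_equal(res$pop_mean_scores[pop, c], mean(sc))
      expect_gte(res$pop_mean_scores[pop, c], min(sc))
      expect_lte(res$pop_mean_scores[pop, c], max(sc))
    }
  }
  # singleton population mean equals the individual
  pm1 <- population_map(p$samples, c("solo", rep("rest", 5)), "c")
  r1 <- population_mean_scores(pca_panel(p, n_components = 2), pm1)
  expect_equal(unname(r1$pop_mean_scores["solo", ]), unname(r1$scores[1, ]))
})

test_that("admixed individuals land between the pure population means on PC1", {
  sim <- simulate_panel(sim_config(n_populations = 2, samples_per_population = 40,
                                   n_snps = 1000, drift_f = 0.3, n_admixed = 15,
                                   admix_dirichlet_alpha = c(1, 1), seed = 24))
  res <- population_mean_scores(pca_panel(sim$panel), sim$pops)
  m <- res$pop_mean_scores[, 1]
  lo <- min(m[c("pop1", "pop2")]); hi <- max(m[c("pop1", "pop2")])
  adm <- res$scores[grep("^admixed", rownames(res$scores)), 1]
  expect_true(all(adm > lo & adm < hi))
})

test_that("the admixture log-likelihood matches direct summation and is label symmetric", {
  p <- hwe_panel(10, 30, 0.4, seed = 25)
  set.seed(26)
  q <- matrix(runif(20), 10, 2); q <- q / rowSums(q)
  f <- matrix(runif(60, 0.05, 0.95), 2, 30)
  # independent oracle: elementwise double loop
  h <- q %*% f
  ll_direct <- 0
  for (i in 1:10) for (j in 1:30) {
    g <- p$dosages[i, j]
    ll_direct <- ll_direct + g * log(h[i, j]) + (2 - g) * log(1 - h[i, j])
  }
  expect_equal(admixture_loglik(p, q, f), ll_direct, tolerance = 1e-10)
  # permuting components leaves it unchanged
  expect_equal(admixture_loglik(p, q[, 2:1], f[2:1, ]),
               admixture_loglik(p, q, f))
  expect_error(admixture_loglik(p, q, f[, 1:10]), "dimension")
})

test_that("K = 1 has the closed-form maximum: f equals half the mean dosage", {
  p <- hwe_panel(20, 50, 0.35, seed = 27)
  fit <- admixture_fit(p, 1, seed = 1)
  expect_equal(unname(fit$q_matrix[, 1]), rep(1, 20))
  expect_equal(unname(fit$f_matrix[1, ]), unname(colMeans(p$dosages) / 2),
               tolerance = 1e-12)
  expect_lte(fit$n_iter, 3)
  # saturated K=1 log-likelihood equals the direct binomial computation
  f <- colMeans(p$dosages) / 2
  h <- pmin(pmax(f, 1e-10), 1 - 1e-10)
  ll <- sum(t(p$dosages) * log(h) + (2 - t(p$dosages)) * log(1 - h))
  expect_equal(fit$loglik, ll, tolerance = 1e-8)
})

test_that("EM is deterministic given a seed and monotone in log-likelihood", {
  sim <- simulate_panel(sim_config(n_populations = 2, samples_per_population = 15,
                                   n_snps = 200, drift_f = 0.3, seed = 28))
  f1 <- admixture_fit(sim$panel, 2, seed = 7)
  f2 <- admixture_fit(sim$panel, 2, seed = 7)
  expect_identical(f1$q_matrix, f2$q_matrix)
  expect_identical(f1$loglik, f2$loglik)
  expect_true(all(diff(f1$loglik_trace) >= -1e-8 * abs(f1$loglik)))
  expect_error(admixture_fit(sim$panel, 100, seed = 1), "exceeds")
})

test_that("EM recovers ancestry proportions in a two-population admixture design", {
  sim <- simulate_panel(sim_config(n_populations = 2, samples_per_population = 40,
                                   n_snps = 1000, drift_f = 0.2, n_admixed = 20,
                                   admix_dirichlet_alpha = c(1, 1), seed = 29))
  fits <- lapply(1:3, function(s) admixture_fit(sim$panel, 2, seed = s))
  best <- fits[[which.max(vapply(fits, `[[`, numeric(1), "loglik"))]]
  qm <- match_components(best$q_matrix, sim$truth$true_q)
  expect_lt(mean(abs(qm - sim$truth$true_q)), 0.05)
  expect_true(all(abs(rowSums(best$q_matrix) - 1) < 1e-6))
  expect_true(all(best$f_matrix >= 0 & best$f_matrix <= 1))
})

test_that("EM skips masked cells: fits use only observed entries", {
  p <- hwe_panel(30, 100, 0.4, seed = 30)
  masked <- inject_missingness(p, 0.2, seed = 31)$panel
  fit <- admixture_fit(masked, 1, seed = 1)
  # K=1 closed form over observed cells only
  expect_equal(unname(fit$f_matrix[1, ]),
               unname(colMeans(masked$dosages, na.rm = TRUE) / 2),
               tolerance = 1e-12)
})

test_that("CV error is non-negative and its K=1 value matches the binomial benchmark", {
  p <- hwe_panel(40, 200, 0.35, seed = 32)
  cv <- admixture_cv(p, 1:2, mask_fraction = 0.1, n_folds = 3, seed = 33)
  expect_true(all(cv$cv_table$cv_error >= 0))
  # at K=1 the predictor is 2 p_hat; the masked MSE should be close to the
  # binomial variance benchmark mean((g - 2 p_hat)^2)
  p_hat <- colMeans(p$dosages) / 2
  bench <- mean((sweep(p$dosages, 2, 2 * p_hat))^2)
  k1 <- cv$cv_table$cv_error[cv$cv_table$k == 1]
  expect_lt(abs(k1 - bench) / bench, 0.15)
})

test_that("cross-validation selects the generating K for well-separated populations", {
  hits <- 0
  for (s in 1:3) {
    sim <- simulate_panel(sim_config(n_populations = 3, samples_per_population = 25,
                                     n_snps = 300, drift_f = 0.3, seed = 800 + s))
    cv <- admixture_cv(sim$panel, 2:4, mask_fraction = 0.1, n_folds = 3,
                       seed = s)
    if (cv$best_k == 3) hits <- hits + 1
  }
  expect_gte(hits, 2)
})
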