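test_that("exact NB test matches exhaustive enumeration on a toy gene", {
  # two libraries per group, equal sizes, group sums 2 and 20 (s = 22)
  y <- c(1, 1, 10, 10)
  groups <- factor(c(1, 1, 2, 2))
  phi <- 0.5
  p <- exact_nb_test(y, groups, phi, rep(1, 4))
  # oracle: sums A, B ~ NB(2 mu0, phi/2); enumerate all 23 splits of s = 22
  s <- 22; mu0 <- s / 4
  lp <- dnbinom(0:s, size = 2 / phi, mu = 2 * mu0, log = TRUE) +
    dnbinom(s:0, size = 2 / phi, mu = 2 * mu0, log = TRUE)
  pr <- exp(lp - max(lp))
  expect_equal(p, sum(pr[lp <= lp[3] + 1e-9]) / sum(pr), tolerance = 1e-10)

  # modal balanced split has p = 1
  expect_equal(exact_nb_test(c(5, 5, 5, 5), groups, 0.5, rep(1, 4)), 1)
  # empty gene flagged as p = 1
  expect_equal(exact_nb_test(c(0, 0, 0, 0), groups, 0.5, rep(1, 4)), 1)
})

test_that("exact test reduces to the binomial-conditioned Poisson test at phi = 0", {
  y <- c(2, 1, 0, 9, 14, 11)
  groups <- toy_groups()
  p <- exact_nb_test(y, groups, 0, rep(1, 6))
  s <- sum(y); a <- 3
  pr <- dbinom(0:s, s, 0.5)
  expect_equal(p, sum(pr[pr <= pr[a + 1] * (1 + 1e-12)]), tolerance = 1e-8)
})

test_that("exact test p-values are monotone in the tail", {
  groups <- factor(c(1, 1, 2, 2))
  s <- 30
  ps <- vapply(0:15, function(a)
    exact_nb_test(c(a, 0, s - a, 0), groups, 0.3, rep(1, 4)), numeric(1))
  # moving the observed split toward the tail (a away from s/2) never raises p
  expect_true(all(diff(ps) >= -1e-12))
})

test_that("large totals use a windowed enumeration that agrees with the full sum", {
  y <- c(40100, 39900, 60200, 59800)
  groups <- factor(c(1, 1, 2, 2))
  p_win <- exact_nb_test(y, groups, 0.05, rep(1, 4))
  # trusted full enumeration at these sizes
  s <- sum(y); mu0 <- s / 4
  lp <- dnbinom(0:s, size = 2 / 0.05, mu = 2 * mu0, log = TRUE) +
    dnbinom(s:0, size = 2 / 0.05, mu = 2 * mu0, log = TRUE)
  pr <- exp(lp - max(lp))
  obs <- sum(y[groups == 1])
  p_full <- sum(pr[lp <= lp[obs + 1] + 1e-9]) / sum(pr)
  expect_equal(p_win, p_full, tolerance = 1e-8)
})

test_that("genewise exact testing records metadata and handles ties", {
  sim <- small_sim(n_genes = 200, seed = 19)
  fit <- estimate_dispersions(sim$counts, sim$groups, "qcml.common")
  res <- run_exact_test(sim$counts, sim$groups, fit, "equalized")
  expect_s3_class(res, "de_test")
  expect_identical(res$test, "exact.equalized")
  expect_identical(res$dispersion_method, "qcml.common")
  expect_true(all(res$p_values >= 0 & res$p_values <= 1))
  res2 <- run_exact_test(sim$counts, sim$groups, fit, "factored")
  expect_identical(res2$test, "exact.factored")
  # equal per-group counts give p = 1
  y1 <- matrix(c(7, 7, 7, 7, 7, 7), 1)
  f1 <- nbdispbench:::new_dispersion_fit(0.4, "true", "truth")
  r1 <- run_exact_test(y1, sim$groups, f1, "equalized", normalization = "none")
  expect_equal(unname(r1$p_values), 1)
})

test_that("quasi-dispersions calibrate near 1 under the NB model", {
  sim <- const_phi_sim(0.15, n_genes = 800, group_sizes = c(6, 6), seed = 61,
                       de_fraction = 0.2)
  fit <- nbdispbench:::new_dispersion_fit(sim$truth$phi, "true", "truth",
                                          gene_ids = rownames(sim$counts))
  qf <- quasi_fit(sim$counts, sim$groups, fit)
  expect_true(all(qf$sigma2_raw > 0))
  expect_gt(median(qf$sigma2_raw), 0.8)
  expect_lt(median(qf$sigma2_raw), 1.2)
  # extra-NB noise (multiplicative log-normal) inflates the quasi-dispersions
  set.seed(9)
  noisy <- round(sim$counts * matrix(exp(rnorm(length(sim$counts), 0, 0.5)),
                                     nrow(sim$counts)))
  storage.mode(noisy) <- "integer"
  qf2 <- quasi_fit(noisy, sim$groups, fit)
  expect_gt(median(qf2$sigma2_raw), median(qf$sigma2_raw) + 0.2)
  # no replication: hard error
  expect_error(quasi_fit(sim$counts[, c(1, 7)], factor(c(1, 2)), fit),
               "replication")
})

test_that("QL F statistic equals the deviance difference when sigma2 is 1", {
  sim <- small_sim(n_genes = 120, seed = 19)
  fit <- nbdispbench:::new_dispersion_fit(sim$truth$phi, "true", "truth",
                                          gene_ids = rownames(sim$counts))
  res <- ql_family_test(sim$counts, sim$groups, fit, "QL", sigma2 = 1,
                        normalization = "none")
  g <- 11
  phi <- sim$truth$phi[g]
  y <- sim$counts[g, ]
  sizes <- rep(sum(sim$counts) / 6, 6)   # "none" normalization sizes
  dev_of <- function(mu) 2 * sum(ifelse(y > 0, y * log(y / mu), 0) -
                                   (y + 1 / phi) * log((y + 1 / phi) / (mu + 1 / phi)))
  lam_full <- vapply(levels(sim$groups), function(lev) {
    idx <- sim$groups == lev
    optimize(function(l) sum(nb_log_pmf(y[idx], l * sizes[idx], phi)),
             c(1e-9, 10), maximum = TRUE, tol = 1e-12)$maximum
  }, numeric(1))
  mu_full <- lam_full[as.integer(sim$groups)] * sizes
  lam0 <- optimize(function(l) sum(nb_log_pmf(y, l * sizes, phi)),
                   c(1e-9, 10), maximum = TRUE, tol = 1e-12)$maximum
  expect_equal(unname(res$statistic[g]), dev_of(lam0 * sizes) - dev_of(mu_full),
               tolerance = 1e-5)
})

test_that("QLShrink limits collapse onto a fixed-denominator F test", {
  sim <- small_sim(n_genes = 200, seed = 19)
  fit <- estimate_dispersions(sim$counts, sim$groups, "qcml.common")
  res_inf <- ql_family_test(sim$counts, sim$groups, fit, "QLShrink",
                            prior_df = Inf)
  qf <- quasi_fit(sim$counts, sim$groups, fit)
  bias <- digamma(qf$df_resid / 2) - log(qf$df_resid / 2)
  target <- exp(mean(log(qf$sigma2_raw)) - bias)
  Fexp <- pmax(qf$dev_reduced - qf$dev_full, 0) / target
  expect_equal(unname(res_inf$statistic), unname(Fexp), tolerance = 1e-8)
  expect_equal(unname(res_inf$p_values),
               pf(Fexp, 1, Inf, lower.tail = FALSE), tolerance = 1e-10)
})

test_that("all five tests return valid p-values for every estimator", {
  sim <- small_sim(n_genes = 200, seed = 19)
  tests <- c("exact.equalized", "exact.factored", "QL", "QLShrink", "QLSpline")
  for (m in c("ql.genewise", "qcml.common", "mom.maximum", "dss")) {
    fit <- estimate_dispersions(sim$counts, sim$groups, m)
    for (te in tests) {
      r <- run_de_test(sim$counts, sim$groups, fit, te)
      expect_true(all(is.finite(r$p_values) & r$p_values >= 0 &
                        r$p_values <= 1), info = paste(m, te))
    }
  }
})

test_that("the QL test is more robust to the dispersion input than the exact test", {
  sim <- small_sim(n_genes = 1000, group_sizes = c(3, 3), seed = 67)
  f_true <- nbdispbench:::new_dispersion_fit(sim$truth$phi, "true", "truth",
                                             gene_ids = rownames(sim$counts))
  f_common <- estimate_dispersions(sim$counts, sim$groups, "qcml.common")
  cor_of <- function(test) {
    p1 <- run_de_test(sim$counts, sim$groups, f_true, test)$p_values
    p2 <- run_de_test(sim$counts, sim$groups, f_common, test)$p_values
    cor(p1, p2, method = "spearman")
  }
  expect_gt(cor_of("QL"), cor_of("exact.equalized"))
})
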