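# Oracle-equivalence and property tests for the ten dispersion estimators.

test_that("QL genewise solves the moment equation (grid-search oracle)", {
  y <- matrix(c(1, 2, 3, 10, 20, 30), nrow = 1)
  groups <- toy_groups()
  sizes <- rep(100, 6)
  fit <- ql_genewise(y, groups, sizes)
  # independent alternation: group means by direct likelihood maximization,
  # phi by bisection of the Pearson equation on a fine grid
  phi <- 0.01
  for (it in 1:100) {
    mus <- numeric(6)
    for (lev in levels(groups)) {
      idx <- which(groups == lev)
      lam <- optimize(function(l) sum(nb_log_pmf(y[1, idx], l * sizes[idx], phi)),
                      c(1e-8, 10), maximum = TRUE, tol = 1e-12)$maximum
      mus[idx] <- lam * sizes[idx]
    }
    f <- function(p) sum((y[1, ] - mus)^2 / (mus + p * mus^2)) - 4
    phi_new <- if (f(0) <= 0) 1e-4 else uniroot(f, c(1e-8, 100), tol = 1e-12)$root
    if (abs(log(phi_new) - log(phi)) < 1e-10) break
    phi <- phi_new
  }
  expect_equal(log(fit$phi[1]), log(phi), tolerance = 1e-4)
})

test_that("QL genewise floors non-overdispersed genes to a common value", {
  sim <- const_phi_sim(0, n_genes = 300, group_sizes = c(6, 6), seed = 3)
  fit <- ql_genewise(sim$counts, sim$groups, rep(mean(colSums(sim$counts)), 12))
  expect_gt(mean(fit$aux$floored), 0.5)
  floored_vals <- unique(fit$phi[fit$aux$floored])
  expect_length(floored_vals, 1)             # the "vertical bar"
})

test_that("conditional likelihood matches a convolution oracle", {
  # one group, counts (3, 5): log[ P(3) P(5) / P(sum = 8) ]
  phi <- 0.4; mu <- 3.7   # any mean: the conditional is mean-free
  conv <- sum(exp(nb_log_pmf(0:8, mu, phi) + nb_log_pmf(8:0, mu, phi)))
  oracle <- nb_log_pmf(3, mu, phi) + nb_log_pmf(5, mu, phi) - log(conv)
  expect_equal(qcml_conditional_loglik(c(3, 5), c(1, 1), phi), oracle,
               tolerance = 1e-8)
  # exchangeability within groups
  g <- factor(c(1, 1, 1, 2, 2, 2))
  expect_equal(qcml_conditional_loglik(c(4, 7, 2, 9, 9, 1), g, 0.3),
               qcml_conditional_loglik(c(2, 4, 7, 9, 1, 9), g, 0.3))
  # single-library groups are degenerate: constant in phi
  v1 <- qcml_conditional_loglik(c(5, 9), factor(c(1, 2)), 0.1)
  v2 <- qcml_conditional_loglik(c(5, 9), factor(c(1, 2)), 3)
  expect_equal(v1, v2)
})

test_that("common qCML maximizes the summed conditional likelihood", {
  m <- toy_counts()
  groups <- toy_groups()
  sizes <- rep(50, 6)   # equal sizes: quantile adjustment is the identity
  fit <- qcml_common(m, groups, sizes)
  grid <- exp(seq(log(1e-4), log(20), length.out = 20000))
  obj <- vapply(grid, function(p)
    sum(vapply(1:4, function(g) qcml_conditional_loglik(m[g, ], groups, p),
               numeric(1))), numeric(1))
  expect_equal(unname(log(fit$phi[1])), log(grid[which.max(obj)]), tolerance = 1e-3)
  expect_length(unique(fit$phi), 1)
  # G = 1 reduces to the single-gene conditional MLE
  fit1 <- qcml_common(m[2, , drop = FALSE], groups, sizes)
  obj1 <- vapply(grid, function(p) qcml_conditional_loglik(m[2, ], groups, p),
                 numeric(1))
  expect_equal(unname(log(fit1$phi[1])), log(grid[which.max(obj1)]), tolerance = 1e-3)
})

test_that("weighted tagwise qCML interpolates between genewise and common", {
  sim <- small_sim(n_genes = 200, seed = 19)
  sizes <- rep(100, 6)    # equal sizes: pseudo-counts equal the raw counts
  f0 <- wqcml_tagwise(sim$counts, sim$groups, sizes, prior_weight = 0)
  fC <- qcml_common(sim$counts, sim$groups, sizes)
  fbig <- wqcml_tagwise(sim$counts, sim$groups, sizes, prior_weight = 1e6)
  expect_true(all(abs(log(fbig$phi) - log(fC$phi[1])) < 1e-3))
  fmid <- wqcml_tagwise(sim$counts, sim$groups, sizes, prior_weight = 5)
  lo <- pmin(log(f0$phi), log(fC$phi[1])) - 1e-6
  hi <- pmax(log(f0$phi), log(fC$phi[1])) + 1e-6
  expect_true(all(log(fmid$phi) >= lo & log(fmid$phi) <= hi))
  # W = 0 equals per-gene conditional MLEs (direct optimize oracle)
  for (g in c(1, 7, 33)) {
    mle <- optimize(function(lp) qcml_conditional_loglik(sim$counts[g, ],
                                                         sim$groups, exp(lp)),
                    log(c(1e-6, 50)), maximum = TRUE, tol = 1e-8)$maximum
    expect_equal(unname(log(f0$phi[g])), mle, tolerance = 1e-3)
  }
})

test_that("APL matches a brute-force (beta, phi) grid on a one-group gene", {
  y <- c(4, 9, 2, 7)
  X <- matrix(1, 4, 1)
  sizes <- rep(10, 4)
  # implementation: profile APL maximized over phi
  opt <- optimize(function(lp) apl(y, X, sizes, exp(lp)), log(c(1e-4, 20)),
                  maximum = TRUE, tol = 1e-9)
  # oracle: dense 2-D grid over beta and phi of loglik - 0.5 log(sum w)
  bgrid <- seq(log(mean(y) / 10) - 1, log(mean(y) / 10) + 1, length.out = 800)
  pgrid <- exp(seq(log(1e-4), log(20), length.out = 3000))
  best <- -Inf; best_p <- NA
  for (p in pgrid) {
    ll <- vapply(bgrid, function(b) {
      mu <- exp(b) * sizes
      sum(nb_log_pmf(y, mu, p)) - 0.5 * log(sum(mu / (1 + p * mu)))
    }, numeric(1))
    if (max(ll) > best) { best <- max(ll); best_p <- p }
  }
  expect_equal(opt$maximum, log(best_p), tolerance = 2e-3)
  # 1x1 information: adjustment is -0.5 log sum w at the fitted mean
  lam <- optimize(function(l) sum(nb_log_pmf(y, l * sizes, 0.5)),
                  c(1e-6, 10), maximum = TRUE, tol = 1e-12)$maximum
  mu <- lam * sizes
  expect_equal(apl(y, X, sizes, 0.5),
               sum(nb_log_pmf(y, mu, 0.5)) - 0.5 * log(sum(mu / (1 + 0.5 * mu))),
               tolerance = 1e-6)
})

test_that("vectorized group APL equals the generic GLM path", {
  m <- toy_counts(); groups <- toy_groups()
  sizes <- c(90, 110, 100, 95, 105, 100)
  X <- cbind(as.numeric(groups == 1), as.numeric(groups == 2))
  for (g in 1:3) {
    for (phi in c(0.05, 0.5, 2)) {
      expect_equal(
        unname(nbdispbench:::apl_group_vec(m[g, , drop = FALSE], groups, sizes, phi)[1]),
        as.numeric(apl(m[g, ], X, sizes, phi)), tolerance = 1e-6)
    }
  }
  # balanced saturated case: fitted means reproduce the group means exactly
  yy <- matrix(rep(6, 4), 1)
  mu <- nbdispbench:::fit_group_means(yy, factor(c(1, 1, 2, 2)), rep(2, 4), 0.3)
  expect_equal(drop(mu), rep(6, 4), tolerance = 1e-6)
})

test_that("common APL recovers a shared dispersion and tracks common qCML", {
  sim <- const_phi_sim(0.1, n_genes = 800, group_sizes = c(5, 5), seed = 41)
  sizes <- adjusted_lib_sizes(sim$counts, median_of_ratios(sim$counts))
  fa <- apl_common(sim$counts, sim$groups, sizes)
  expect_lt(abs(fa$phi[1] - 0.1), 0.03)
  fq <- qcml_common(sim$counts, sim$groups, sizes)
  expect_lt(abs(log(fa$phi[1] / fq$phi[1])), log(1.2))
})

test_that("trended APL is a function of abundance with bounded fit", {
  sim <- const_phi_sim(0.15, n_genes = 600, group_sizes = c(4, 4), seed = 43)
  sizes <- adjusted_lib_sizes(sim$counts, median_of_ratios(sim$counts))
  fit <- apl_trended(sim$counts, sim$groups, sizes)
  # flat truth: fitted trend nearly flat
  expect_lt(diff(range(log(fit$phi))), 0.6)
  expect_true(all(log(fit$phi) >= min(fit$aux$trend$log_phi) - 1e-8))
  expect_true(all(log(fit$phi) <= max(fit$aux$trend$log_phi) + 1e-8))
  expect_error(apl_trended(sim$counts[1:10, ], sim$groups, sizes), "too few")
})

test_that("tagwise APL interpolates between genewise and neighborhood APL", {
  sim <- small_sim(n_genes = 160, seed = 19)
  sizes <- adjusted_lib_sizes(sim$counts, median_of_ratios(sim$counts))
  f0 <- apl_tagwise(sim$counts, sim$groups, sizes, prior_weight = 0)
  fbig <- apl_tagwise(sim$counts, sim$groups, sizes, prior_weight = 1e6)
  fmid <- apl_tagwise(sim$counts, sim$groups, sizes, prior_weight = 5)
  lo <- pmin(log(f0$phi), log(fbig$phi)) - 0.02
  hi <- pmax(log(f0$phi), log(fbig$phi)) + 0.02
  expect_gt(mean(log(fmid$phi) >= lo & log(fmid$phi) <= hi), 0.95)
  # W = 0 equals the genewise APL maximizer
  for (g in c(2, 50)) {
    mle <- optimize(function(lp)
      nbdispbench:::apl_group_vec(sim$counts[g, , drop = FALSE], sim$groups,
                                  sizes, exp(lp)),
      log(c(1e-6, 50)), maximum = TRUE, tol = 1e-8)$maximum
    expect_equal(unname(log(f0$phi[g])), mle, tolerance = 1e-3)
  }
})

test_that("method-of-moments genewise matches the stated formulas", {
  y <- matrix(c(10, 20, 30), 1)
  fit <- mom_genewise(y, factor(c(1, 1, 1)), c(1, 1, 1))
  # q = 20, w = 100, z = 20, v = 80, phi = 80/400
  expect_equal(unname(fit$phi[1]), 0.2)
  expect_equal(unname(fit$aux$q[1]), 20)
  expect_equal(unname(fit$aux$v[1]), 80)
  # Poisson data: bias term cancels the sampling variance, most at floor
  sim <- const_phi_sim(0, n_genes = 400, group_sizes = c(8, 8), seed = 47)
  fp <- mom_genewise(sim$counts, sim$groups, rep(1, 16))
  expect_gt(mean(fp$phi <= 1e-4 + 1e-12), 0.4)
  # invariance to relabeling libraries within a group
  perm <- c(3, 1, 2, 4:16)
  fp2 <- mom_genewise(sim$counts[, perm], sim$groups[perm], rep(1, 16))
  expect_equal(fp$phi, fp2$phi)
})

test_that("trended and maximum method-of-moments respect their contracts", {
  sim <- const_phi_sim(0.2, n_genes = 500, group_sizes = c(4, 4), seed = 53)
  cf <- median_of_ratios(sim$counts)
  tr <- mom_trended(sim$counts, sim$groups, cf)
  gw <- mom_genewise(sim$counts, sim$groups, cf)
  mx <- mom_maximum(sim$counts, sim$groups, cf)
  expect_true(all(mx$phi >= gw$phi - 1e-12))
  expect_true(all(mx$phi >= tr$phi - 1e-12))
  expect_gt(mean(mx$phi), mean(tr$phi))
  # two genes with equal normalized mean get equal trended dispersion
  y2 <- rbind(sim$counts, sim$counts[7, ], sim$counts[7, ])
  tr2 <- mom_trended(y2, sim$groups, cf)
  n <- nrow(y2)
  expect_equal(unname(tr2$phi[n - 1]), unname(tr2$phi[n]))
  # flat truth gives a nearly flat fitted trend
  mid <- gw$aux$q > quantile(gw$aux$q, 0.1)
  expect_lt(diff(range(log(tr$phi[mid]))), 1)
})

test_that("posterior-mode estimator matches a grid oracle and shrinks to the prior", {
  y <- matrix(c(3, 8, 1, 14, 25, 9), 1)
  groups <- toy_groups()
  fit <- dss(y, groups, rep(1, 6), prior_log_mean = log(0.3), prior_log_sd = 0.7)
  pgrid <- exp(seq(log(1e-5), log(30), length.out = 6000))
  obj <- vapply(pgrid, function(p) {
    ll <- 0
    for (lev in levels(groups)) {
      idx <- which(groups == lev)
      lam <- optimize(function(l) sum(nb_log_pmf(y[1, idx], rep(l, 3), p)),
                      c(1e-6, 100), maximum = TRUE, tol = 1e-10)$maximum
      ll <- ll + sum(nb_log_pmf(y[1, idx], rep(lam, 3), p))
    }
    ll + dlnorm(p, log(0.3), 0.7, log = TRUE)
  }, numeric(1))
  expect_equal(unname(log(fit$phi[1])), log(pgrid[which.max(obj)]), tolerance = 3e-3)
  # degenerate prior dominates
  f0 <- dss(y, groups, rep(1, 6), prior_log_mean = log(0.3), prior_log_sd = 0)
  expect_equal(unname(f0$phi[1]), 0.3)
  # the posterior mode lies between the profile-likelihood maximizer and the
  # prior mode, pulled toward the prior
  sim <- small_sim(n_genes = 200, seed = 19)
  fd <- dss(sim$counts, sim$groups, rep(1, 6))
  prior_mode <- fd$aux$prior_log_mean - fd$aux$prior_log_sd^2
  for (g in seq(1, 200, by = 13)) {
    yg <- sim$counts[g, , drop = FALSE]
    lmle <- optimize(function(lp) {
      mu <- nbdispbench:::fit_group_means(yg, sim$groups, rep(1, 6), exp(lp))
      nb_loglik(drop(yg), drop(mu), exp(lp))
    }, log(c(1e-6, 50)), maximum = TRUE, tol = 1e-8)$maximum
    lhat <- unname(log(fd$phi[g]))
    expect_gte(lhat, min(lmle, prior_mode) - 0.02)
    expect_lte(lhat, max(lmle, prior_mode) + 0.02)
  }
})

test_that("every estimator satisfies the shrinkage-taxonomy invariants", {
  sim <- small_sim(n_genes = 200, seed = 19)
  fits <- lapply(names(dispersion_methods()), function(m)
    estimate_dispersions(sim$counts, sim$groups, m))
  names(fits) <- names(dispersion_methods())
  for (m in names(fits)) {
    f <- fits[[m]]
    expect_true(all(is.finite(f$phi)) && all(f$phi >= 1e-4 - 1e-15), info = m)
    expect_identical(f$shrinkage, unname(dispersion_methods()[m]), info = m)
  }
  for (m in c("qcml.common", "apl.common"))
    expect_length(unique(fits[[m]]$phi), 1)
  expect_true(all(fits$mom.maximum$phi >= fits$mom.trended$phi - 1e-12))
  # gene-order invariance
  perm <- sample(nrow(sim$counts))
  for (m in c("mom.genewise", "ql.genewise", "dss", "apl.trended")) {
    fp <- estimate_dispersions(sim$counts[perm, ], sim$groups, m)
    expect_equal(unname(fp$phi), unname(fits[[m]]$phi[perm]), tolerance = 1e-8,
                 info = m)
  }
})
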