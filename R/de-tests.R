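# Tests for differential expression: NB exact tests (conditioning the group
# sums on their total) in library-size-equalized and factor-based variants,
# and the quasi-likelihood F-test family (QL, QLShrink, QLSpline).

new_de_test <- function(p_values, statistic, test, dispersion_method,
                        gene_ids = NULL) {
  if (!is.null(gene_ids)) names(p_values) <- gene_ids
  structure(list(p_values = p_values, statistic = statistic, test = test,
                 dispersion_method = dispersion_method),
            class = "de_test")
}

#' @export
print.de_test <- function(x, ...) {
  cat("DE test:", x$test, " (dispersions:", x$dispersion_method, ")\n")
  cat("  genes:", length(x$p_values),
      "  p < 0.05:", sum(x$p_values < 0.05), "\n")
  invisible(x)
}

#' Write DE test results as TSV
#'
#' Columns: \code{gene_id, statistic, p_value, test, dispersion_method}.
#'
#' @param result A \code{de_test}.
#' @param path File path.
#' @return The path, invisibly.
#' @export
write_de_test <- function(result, path) {
  ids <- names(result$p_values)
  if (is.null(ids)) ids <- sprintf("gene%05d", seq_along(result$p_values))
  utils::write.table(
    data.frame(gene_id = ids, statistic = result$statistic,
               p_value = result$p_values, test = result$test,
               dispersion_method = result$dispersion_method),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Log pmf of a group sum: the sum of the group's library sizes and the
# variance-matched dispersion give A ~ NB(mu0 * C, phi * sum(c^2)/C^2); for
# equal sizes this is the exact NB(n mu0, phi/n) closed form for a sum of
# i.i.d. NB variables.
group_sum_params <- function(sizes, phi) {
  C <- sum(sizes)
  list(C = C, phi = phi * sum(sizes^2) / C^2)
}

#' Exact NB test for one gene
#'
#' Conditional test of equal normalized group means. The two group sums are
#' modeled as NB with a shared per-unit-size mean estimated under the null;
#' conditioning on their total, the p-value is the probability of all splits
#' whose probability does not exceed the observed split's (the
#' doubling-free two-sided rule; a doubled-smaller-tail rule is available).
#'
#' @param y Count vector for one gene.
#' @param groups Group labels (two levels).
#' @param phi Dispersion for this gene.
#' @param effective_sizes Per-library sizes (equal sizes give the exact sum
#'   distribution; unequal sizes are handled by variance matching).
#' @param tail_rule \code{"smallp"} (default) or \code{"doubled"}.
#' @return Two-sided p-value in [0, 1].
#' @export
exact_nb_test <- function(y, groups, phi, effective_sizes,
                          tail_rule = c("smallp", "doubled")) {
  tail_rule <- match.arg(tail_rule)
  groups <- as.factor(groups)
  if (nlevels(groups) != 2L) stop("exact test needs exactly two groups")
  idxA <- groups == levels(groups)[1]
  a <- sum(y[idxA]); b <- sum(y[!idxA])
  s <- a + b
  if (s == 0) return(1)
  sizes <- rep_len(effective_sizes, length(y))
  pa <- group_sum_params(sizes[idxA], phi)
  pb <- group_sum_params(sizes[!idxA], phi)
  mu0 <- s / (pa$C + pb$C)
  muA <- mu0 * pa$C; muB <- mu0 * pb$C
  lp <- function(av) sum_log_pmf(av, muA, pa$phi) + sum_log_pmf(s - av, muB, pb$phi)
  av <- split_support(s, muA, pa$phi, muB, pb$phi)
  lpv <- lp(av)
  m <- max(lpv)
  pr <- exp(lpv - m)
  tot <- sum(pr)
  lp_obs <- lp(a)
  if (tail_rule == "smallp") {
    sum(pr[lpv <= lp_obs + 1e-9]) / tot
  } else {
    cum <- cumsum(pr) / tot
    i <- match(a, av)
    lowtail <- cum[i]
    hightail <- 1 - if (i > 1) cum[i - 1] else 0
    min(1, 2 * min(lowtail, hightail))
  }
}

sum_log_pmf <- function(y, mu, phi) {
  if (phi < .PHI_POISSON) stats::dpois(y, mu, log = TRUE)
  else stats::dnbinom(y, size = 1 / phi, mu = mu, log = TRUE)
}

# Support over which conditional split probabilities are enumerated.  Full
# enumeration up to moderate totals; for very large totals, a window around
# the conditional mode wide enough that excluded terms underflow double
# precision relative to the mode (they change neither tail sums nor the
# normalizing constant at working precision).
split_support <- function(s, muA, phiA, muB, phiB, cap = 100000) {
  if (s <= cap) return(0:s)
  qa <- if (phiA < .PHI_POISSON)
    stats::qpois(c(1e-305, 1 - 1e-14), muA) else
    stats::qnbinom(c(1e-305, 1 - 1e-14), size = 1 / phiA, mu = muA)
  qb <- if (phiB < .PHI_POISSON)
    stats::qpois(c(1e-305, 1 - 1e-14), muB) else
    stats::qnbinom(c(1e-305, 1 - 1e-14), size = 1 / phiB, mu = muB)
  lo <- max(0, qa[1], s - qb[2])
  hi <- min(s, qa[2] + (s - muA - muB), s - qb[1])  # generous upper pad
  unique(pmin(pmax(seq.int(floor(lo), ceiling(hi)), 0), s))
}

#' Run an exact test over all genes
#'
#' The \code{"equalized"} variant quantile-adjusts counts to a common library
#' size before testing (the conditional argument is exact there); the
#' \code{"factored"} variant uses the median-of-ratios factors directly as
#' sizes. Both share the same conditional-test core.
#'
#' @param counts Genes x libraries count matrix.
#' @param groups Group labels.
#' @param fit A \code{dispersion_fit} supplying per-gene dispersions.
#' @param variant \code{"equalized"} or \code{"factored"}.
#' @param normalization Passed through for factor computation when the fit
#'   carries none.
#' @return A \code{de_test}; the statistic is the log2 ratio of normalized
#'   group means.
#' @export
run_exact_test <- function(counts, groups, fit,
                           variant = c("equalized", "factored"),
                           normalization = c("median_of_ratios", "none")) {
  variant <- match.arg(variant)
  normalization <- match.arg(normalization)
  groups <- as.factor(groups)
  phi <- rep_len(fit$phi, nrow(counts))
  cf <- fit$aux$norm_factors
  if (is.null(cf))
    cf <- if (normalization == "none") rep(1, ncol(counts)) else
      median_of_ratios(counts)
  if (variant == "equalized") {
    sizes <- adjusted_lib_sizes(counts, cf)
    qa <- quantile_adjust(counts, sizes, phi)
    y <- qa$values
    test_sizes <- rep(qa$common_size, ncol(counts))
  } else {
    y <- counts
    test_sizes <- cf
  }
  G <- nrow(counts)
  p <- numeric(G)
  for (g in seq_len(G))
    p[g] <- exact_nb_test(y[g, ], groups, phi[g], test_sizes)
  idxA <- groups == levels(groups)[1]
  x <- sweep(counts, 2, cf, "/")
  stat <- log2((rowMeans(x[, idxA, drop = FALSE]) + 0.5) /
               (rowMeans(x[, !idxA, drop = FALSE]) + 0.5))
  new_de_test(p, stat, paste0("exact.", variant), fit$method,
              gene_ids = rownames(counts))
}

#' Quasi-likelihood dispersion fit
#'
#' Fits the full NB GLM (one mean per group) at each gene's fixed NB
#' dispersion and estimates a per-gene quasi-likelihood dispersion as the
#' residual deviance divided by the residual degrees of freedom. When the NB
#' model holds exactly these concentrate near 1; extra-NB noise inflates
#' them.
#'
#' @inheritParams run_exact_test
#' @return List with \code{sigma2_raw}, \code{dev_full}, \code{dev_reduced},
#'   \code{df_resid}, \code{abundance}.
#' @export
quasi_fit <- function(counts, groups, fit,
                      normalization = c("median_of_ratios", "none")) {
  normalization <- match.arg(normalization)
  groups <- as.factor(groups)
  df <- ncol(counts) - nlevels(groups)
  if (df < 1) stop("quasi-likelihood tests require replication (residual df >= 1)")
  phi <- rep_len(fit$phi, nrow(counts))
  cf <- fit$aux$norm_factors
  if (is.null(cf))
    cf <- if (normalization == "none") rep(1, ncol(counts)) else
      median_of_ratios(counts)
  sizes <- adjusted_lib_sizes(counts, cf)
  mu_full <- fit_group_means(counts, groups, sizes, phi)
  lam0 <- fit_group_lambda(counts, sizes, phi)
  mu_red <- outer(lam0, sizes)
  G <- nrow(counts)
  dev_full <- dev_red <- numeric(G)
  for (g in seq_len(G)) {
    dev_full[g] <- nb_deviance(counts[g, ], mu_full[g, ], phi[g])
    dev_red[g] <- nb_deviance(counts[g, ], mu_red[g, ], phi[g])
  }
  list(sigma2_raw = pmax(dev_full / df, 1e-8),
       dev_full = dev_full, dev_reduced = pmax(dev_red, dev_full),
       df_resid = df, abundance = gene_abundance(counts, sizes))
}

# Solve trigamma(x) = y by Newton iteration (monotone decreasing trigamma).
trigamma_inverse <- function(y) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2L)
    x <- x + dif
    if (abs(dif / x) < 1e-10) break
  }
  x
}

# Empirical-Bayes moment matching on log quasi-dispersions: returns the prior
# df and the per-gene shrinkage target (a scalar target, or a vector around a
# fitted trend for the spline flavor).
squeeze_sigma2 <- function(sigma2, df, target_log = NULL, prior_df = NULL) {
  e <- log(sigma2)
  bias <- digamma(df / 2) - log(df / 2)
  if (is.null(target_log)) target_log <- rep(mean(e) - bias, length(e))
  if (is.null(prior_df)) {
    resid_var <- stats::var(e - (target_log + bias))
    excess <- resid_var - trigamma(df / 2)
    prior_df <- if (excess <= 0) Inf else 2 * trigamma_inverse(excess)
  }
  target <- exp(target_log)
  shrunk <- if (is.infinite(prior_df)) target else
    (df * sigma2 + prior_df * target) / (df + prior_df)
  list(sigma2 = shrunk, prior_df = prior_df, target = target)
}

#' Quasi-likelihood F-test family
#'
#' Per gene, an F statistic compares the intercept-only and two-group NB fits
#' at fixed NB dispersion: \code{F = (dev_reduced - dev_full) / sigma2}, with
#' the quasi-dispersion \code{sigma2} taken raw (\code{"QL"}), shrunk toward a
#' common value by empirical-Bayes moment matching on the log scale, which
#' adds \code{prior_df} denominator degrees of freedom (\code{"QLShrink"}), or
#' shrunk toward a cubic-spline fit of log quasi-dispersion on abundance
#' (\code{"QLSpline"}). P-values come from an F distribution with
#' \code{(1, df_resid + prior_df)} degrees of freedom.
#'
#' @inheritParams run_exact_test
#' @param flavor \code{"QL"}, \code{"QLShrink"} or \code{"QLSpline"}.
#' @param prior_df Optional override of the estimated prior df (test hook;
#'   \code{Inf} fixes every quasi-dispersion at its target).
#' @param sigma2 Optional override of the quasi-dispersions (test hook).
#' @param spline_df Effective df of the abundance spline (QLSpline).
#' @return A \code{de_test}; the statistic is the per-gene F value.
#' @export
ql_family_test <- function(counts, groups, fit,
                           flavor = c("QLShrink", "QL", "QLSpline"),
                           prior_df = NULL, sigma2 = NULL, spline_df = 4L,
                           normalization = c("median_of_ratios", "none")) {
  flavor <- match.arg(flavor)
  qf <- quasi_fit(counts, groups, fit, normalization)
  df <- qf$df_resid
  if (flavor == "QL") {
    s2 <- if (is.null(sigma2)) qf$sigma2_raw else rep_len(sigma2, nrow(counts))
    denom_df <- df
  } else {
    target_log <- NULL
    if (flavor == "QLSpline") {
      basis <- splines::ns(qf$abundance, df = spline_df)
      lmfit <- stats::lm.fit(cbind(1, basis), log(qf$sigma2_raw))
      target_log <- drop(cbind(1, basis) %*% lmfit$coefficients) -
        (digamma(df / 2) - log(df / 2))
    }
    sq <- squeeze_sigma2(qf$sigma2_raw, df, target_log = target_log,
                         prior_df = prior_df)
    s2 <- if (is.null(sigma2)) sq$sigma2 else rep_len(sigma2, nrow(counts))
    denom_df <- df + sq$prior_df
  }
  Fstat <- pmax(qf$dev_reduced - qf$dev_full, 0) / s2
  p <- stats::pf(Fstat, 1, denom_df, lower.tail = FALSE)
  p[rowSums(counts) == 0] <- 1
  new_de_test(p, Fstat, flavor, fit$method, gene_ids = rownames(counts))
}

#' Run a registered DE test by name
#'
#' @inheritParams run_exact_test
#' @param test One of \code{"exact.equalized"}, \code{"exact.factored"},
#'   \code{"QL"}, \code{"QLShrink"}, \code{"QLSpline"}.
#' @param ... Passed to the underlying test.
#' @return A \code{de_test}.
#' @export
run_de_test <- function(counts, groups, fit,
                        test = c("exact.equalized", "exact.factored",
                                 "QLShrink", "QL", "QLSpline"), ...) {
  test <- match.arg(test)
  switch(test,
    exact.equalized = run_exact_test(counts, groups, fit, "equalized", ...),
    exact.factored  = run_exact_test(counts, groups, fit, "factored", ...),
    QL              = ql_family_test(counts, groups, fit, "QL", ...),
    QLShrink        = ql_family_test(counts, groups, fit, "QLShrink", ...),
    QLSpline        = ql_family_test(counts, groups, fit, "QLSpline", ...))
}
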