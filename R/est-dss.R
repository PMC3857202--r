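# Empirical-Bayes dispersion shrinkage: a Gamma-Poisson hierarchy whose
# marginal is NB, with a log-normal prior on the dispersion; each estimate is
# the mode of the conditional (posterior) distribution of phi given the
# gene's counts, with prior hyperparameters set by an adapted method of
# moments on the genewise estimates.

.DSS_PHI_RANGE <- c(1e-6, 50)

#' Empirical-Bayes posterior-mode dispersion estimator
#'
#' Hyperparameters of the log-normal prior are estimated by method of moments
#' from the genewise moment estimates: the prior log-mean is the average log
#' genewise dispersion over genes with positive raw variance, and the prior
#' log-variance is the between-gene variance of those log dispersions minus
#' the median estimation noise (approximated by the chi-square log-variance
#' \code{2/df}), floored at 0.01. Each gene's estimate then maximizes the NB
#' profile log likelihood (group means at their MLEs) plus the log prior
#' density, so estimates shrink smoothly toward the prior mode.
#'
#' @inheritParams mom_genewise
#' @param prior_log_mean,prior_log_sd Optional hyperparameter overrides
#'   (test hooks); \code{prior_log_sd = 0} returns the prior mode for every
#'   gene.
#' @return A \code{dispersion_fit}; \code{aux} holds the hyperparameters.
#' @export
dss <- function(counts, groups, norm_factors,
                prior_log_mean = NULL, prior_log_sd = NULL,
                min_dispersion = .DEFAULT_PHI_FLOOR) {
  groups <- as.factor(groups)
  gw <- mom_genewise(counts, groups, norm_factors, min_dispersion)
  ok <- gw$aux$v > 0 & gw$aux$q > 0
  lphi <- log(gw$phi[ok])
  if (is.null(prior_log_mean))
    prior_log_mean <- if (any(ok)) mean(lphi) else log(0.1)
  if (is.null(prior_log_sd)) {
    noise <- 2 / gw$aux$df      # approximate log-scale estimation variance
    s2 <- max(stats::var(lphi) - noise, 0.01)
    prior_log_sd <- sqrt(s2)
  }
  if (prior_log_sd == 0) {
    phi <- rep(max(exp(prior_log_mean), min_dispersion), nrow(counts))
    return(new_dispersion_fit(phi, "dss", "tagwise",
                              aux = list(prior_log_mean = prior_log_mean,
                                         prior_log_sd = 0,
                                         genewise = gw$phi),
                              gene_ids = rownames(counts)))
  }
  sizes <- norm_factors    # factors act as per-library offsets in the GLM mean
  G <- nrow(counts)
  # posterior (penalized profile) objective on a log-phi grid, vectorized
  # across genes, to bracket each gene's mode; the exact objective is then
  # maximized inside its bracket
  grid <- seq(log(.DSS_PHI_RANGE[1]), log(.DSS_PHI_RANGE[2]), length.out = 41)
  obj <- matrix(vapply(grid, function(lp) {
    p <- exp(lp)
    mu <- fit_group_means(counts, groups, sizes, p)
    rowSums(matrix(nb_log_pmf(as.vector(counts), as.vector(mu), p),
                   G, ncol(counts))) +
      stats::dlnorm(p, prior_log_mean, prior_log_sd, log = TRUE)
  }, numeric(G)), nrow = G)
  ng <- length(grid)
  i <- max.col(obj, ties.method = "first")
  i <- pmin(pmax(i, 2L), ng - 1L)
  f <- function(lphi) {
    p <- exp(lphi)
    mu <- fit_group_means(counts, groups, sizes, p)
    rowSums(matrix(nb_log_pmf(as.vector(counts), as.vector(mu),
                              rep(p, ncol(counts))), G, ncol(counts))) +
      stats::dlnorm(p, prior_log_mean, prior_log_sd, log = TRUE)
  }
  lphi <- golden_max_vec(f, grid[i - 1L], grid[i + 1L], tol = 1e-4)
  phi <- exp(lphi)
  failed <- logical(G)
  if (any(failed))
    warning(sum(failed), " gene(s) fell back to the prior mode")
  new_dispersion_fit(pmax(phi, min_dispersion), "dss", "tagwise",
                     aux = list(prior_log_mean = prior_log_mean,
                                prior_log_sd = prior_log_sd,
                                genewise = gw$phi, fallback = failed),
                     gene_ids = rownames(counts))
}
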