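# Quantile-adjusted conditional maximum likelihood: conditional NB likelihood
# given per-group count sums (valid once library sizes are equalized), in a
# common variant and a weighted tagwise variant that shrinks genewise
# dispersions toward the common value.

.QCML_PHI_RANGE <- c(1e-6, 50)

#' Conditional NB log likelihood for one gene
#'
#' Log likelihood of the within-group counts given their group sums, under
#' i.i.d. NB observations with a shared mean and dispersion inside each group,
#' summed over groups. The group means cancel, leaving a log-gamma closed
#' form; groups with a single library contribute zero (conditioning on one
#' observation's own sum is degenerate).
#'
#' @param y Pseudo-count vector for one gene (libraries equalized in size).
#' @param groups Group labels.
#' @param phi Non-negative dispersion.
#' @return Scalar conditional log likelihood.
#' @export
qcml_conditional_loglik <- function(y, groups, phi) {
  unname(drop(cond_loglik_matrix(rbind(y), as.factor(groups), phi)))
}

# Vectorized across genes for a scalar phi: counts is G x J.
cond_loglik_matrix <- function(counts, groups, phi) {
  if (phi < 1e-10) phi <- 1e-10   # conditional form needs a finite size
  r <- 1 / phi
  out <- numeric(nrow(counts))
  for (lev in levels(groups)) {
    idx <- which(groups == lev)
    n <- length(idx)
    if (n < 2L) next
    y <- counts[, idx, drop = FALSE]
    s <- rowSums(y)
    out <- out + rowSums(lgamma(y + r) - lfactorial(y)) - n * lgamma(r) -
      (lgamma(s + n * r) - lfactorial(s) - lgamma(n * r))
  }
  out
}

# Two-pass quantile adjustment: equalize at the current dispersion, then
# re-estimate.  Returns the pseudo-counts and the common dispersion trace.
qcml_pseudo <- function(counts, groups, effective_sizes, n_iter = 2L) {
  phi <- 0.1
  pseudo <- counts
  for (it in seq_len(n_iter)) {
    pseudo <- quantile_adjust(counts, effective_sizes, phi)$values
    phi <- qcml_optimize_common(pseudo, groups)
  }
  list(pseudo = pseudo, common_phi = phi)
}

qcml_optimize_common <- function(pseudo, groups) {
  f <- function(lphi) sum(cond_loglik_matrix(pseudo, groups, exp(lphi)))
  opt <- stats::optimize(f, log(.QCML_PHI_RANGE), maximum = TRUE, tol = 1e-8)
  exp(opt$maximum)
}

#' Common qCML dispersion estimator
#'
#' Equalizes library sizes by quantile adjustment, then maximizes the summed
#' conditional log likelihood over a single dispersion shared by all genes.
#' The adjustment and the common estimate are iterated (twice by default) so
#' the pseudo-counts are computed at a dispersion consistent with the
#' estimate.
#'
#' @inheritParams ql_genewise
#' @param n_iter Quantile-adjustment iterations.
#' @return A \code{dispersion_fit} with a constant \code{phi} vector.
#' @export
qcml_common <- function(counts, groups, effective_sizes, n_iter = 2L,
                        min_dispersion = .DEFAULT_PHI_FLOOR) {
  groups <- as.factor(groups)
  qp <- qcml_pseudo(counts, groups, effective_sizes, n_iter)
  phi <- max(qp$common_phi, min_dispersion)
  new_dispersion_fit(rep(phi, nrow(counts)), "qcml.common", "common",
                     aux = list(common_phi = phi),
                     gene_ids = rownames(counts))
}

#' Weighted tagwise qCML dispersion estimator
#'
#' Maximizes, per gene, the weighted conditional likelihood
#' \code{l_g(phi) + W * l_C(phi)}, where \code{l_C} is the per-gene average
#' common conditional log likelihood, so the prior weight \code{W} is in
#' units of equivalent genes. \code{W = 0} returns genewise conditional MLEs;
#' large \code{W} collapses onto the common estimate.
#'
#' By default \code{W} is set by empirical-Bayes moment matching: the
#' between-gene variance of the genewise log-dispersion maximizers, less the
#' approximate estimation variance, gives the true between-gene spread, and
#' \code{W} balances the prior's precision against it, so a wide true spread
#' yields weak shrinkage and a tight spread strong shrinkage.
#'
#' @inheritParams qcml_common
#' @param prior_weight Shrinkage weight W (equivalent genes); \code{NULL}
#'   (default) applies the moment-matching rule.
#' @return A \code{dispersion_fit}.
#' @export
wqcml_tagwise <- function(counts, groups, effective_sizes, prior_weight = NULL,
                          n_iter = 2L, min_dispersion = .DEFAULT_PHI_FLOOR) {
  stopifnot(is.null(prior_weight) || prior_weight >= 0)
  groups <- as.factor(groups)
  qp <- qcml_pseudo(counts, groups, effective_sizes, n_iter)
  pseudo <- qp$pseudo
  G <- nrow(counts)
  # per-gene conditional log-likelihood curves on a log-phi grid; their
  # per-gene average is the common curve
  grid <- exp(seq(log(.QCML_PHI_RANGE[1]), log(.QCML_PHI_RANGE[2]),
                  length.out = 61))
  curve_mat <- matrix(vapply(grid, function(p)
    cond_loglik_matrix(pseudo, groups, p), numeric(G)), nrow = G)
  lC <- colMeans(curve_mat)
  if (is.null(prior_weight))
    prior_weight <- eb_prior_weight(curve_mat, log(grid),
                                    max(ncol(counts) - nlevels(groups), 1L))
  lC_fun <- stats::splinefun(log(grid), lC, method = "natural")
  lo <- log(.QCML_PHI_RANGE[1]); hi <- log(.QCML_PHI_RANGE[2])
  phi <- numeric(G)
  for (g in seq_len(G)) {
    y <- pseudo[g, , drop = FALSE]
    f <- function(lphi)
      drop(cond_loglik_matrix(y, groups, exp(lphi))) + prior_weight * lC_fun(lphi)
    phi[g] <- exp(stats::optimize(f, c(lo, hi), maximum = TRUE, tol = 1e-6)$maximum)
  }
  new_dispersion_fit(pmax(phi, min_dispersion), "wqcml.tagwise", "tagwise",
                     aux = list(common_phi = qp$common_phi,
                                prior_weight = prior_weight),
                     gene_ids = rownames(counts))
}
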