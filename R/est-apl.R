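# Cox-Reid adjusted profile likelihood (APL) dispersion estimation for the
# log-linear NB model mu_gj = exp(x_j' beta_g) * L_j, in common, trended and
# tagwise (neighborhood-shrunk) variants.

.APL_PHI_RANGE <- c(1e-6, 50)

#' Cox-Reid adjusted profile likelihood for one gene
#'
#' Fits the NB GLM coefficients by iteratively reweighted least squares at a
#' fixed dispersion (log link, log effective size offset) and returns the
#' profile log likelihood minus half the log determinant of the Fisher
#' information \code{X' W X} at the fit, the Cox-Reid adjustment for having
#' estimated the mean parameters.
#'
#' @param y Count vector for one gene.
#' @param design Full-rank design matrix (libraries x coefficients).
#' @param effective_sizes Per-library effective sizes.
#' @param phi Non-negative dispersion.
#' @param max_iter,tol IRLS control.
#' @return Scalar adjusted profile log likelihood.
#' @export
apl <- function(y, design, effective_sizes, phi, max_iter = 50L, tol = 1e-10) {
  X <- as.matrix(design)
  if (qr(X)$rank < ncol(X)) stop("design matrix must have full rank")
  offset <- log(effective_sizes)
  beta <- qr.solve(X, log(pmax(y, 0.5)) - offset)
  mu <- exp(drop(X %*% beta) + offset)
  for (it in seq_len(max_iter)) {
    w <- mu / (1 + phi * mu)
    z <- drop(X %*% beta) + (y - mu) / mu
    fit <- stats::lm.wfit(X, z, w)
    beta_new <- fit$coefficients
    if (any(!is.finite(beta_new))) stop("IRLS produced non-finite coefficients")
    step <- max(abs(beta_new - beta))
    beta <- beta_new
    mu <- exp(drop(X %*% beta) + offset)
    mu <- pmax(mu, 1e-10)
    if (step < tol) break
  }
  if (it == max_iter && step >= 1e-6)
    stop("IRLS did not converge within ", max_iter, " iterations")
  w <- mu / (1 + phi * mu)
  info <- crossprod(X, X * w)
  nb_loglik(y, mu, phi) -
    0.5 * as.numeric(determinant(info, logarithm = TRUE)$modulus)
}

# Vectorized APL across genes for the two-group design, exploiting the fact
# that under a group-indicator parameterization the information matrix is
# diagonal with per-group entries sum_j mu_j / (1 + phi mu_j).
apl_group_vec <- function(counts, groups, sizes, phi) {
  phi <- rep_len(phi, nrow(counts))
  mu <- fit_group_means(counts, groups, sizes, phi)
  ll <- rowSums(matrix(nb_log_pmf(as.vector(counts), as.vector(mu),
                                  rep(phi, ncol(counts))),
                       nrow(counts), ncol(counts)))
  adj <- 0
  w <- mu / (1 + phi * mu)
  for (lev in levels(groups)) {
    idx <- which(groups == lev)
    adj <- adj + log(rowSums(w[, idx, drop = FALSE]))
  }
  ll - 0.5 * adj
}

#' Common APL dispersion estimator
#'
#' One dispersion for all genes, maximizing the arithmetic mean of the
#' per-gene Cox-Reid adjusted profile likelihoods.
#'
#' @inheritParams ql_genewise
#' @return A \code{dispersion_fit} with a constant \code{phi} vector.
#' @export
apl_common <- function(counts, groups, effective_sizes,
                       min_dispersion = .DEFAULT_PHI_FLOOR) {
  groups <- as.factor(groups)
  f <- function(lphi) mean(apl_group_vec(counts, groups, effective_sizes,
                                         exp(lphi)))
  opt <- stats::optimize(f, log(.APL_PHI_RANGE), maximum = TRUE, tol = 1e-8)
  phi <- max(exp(opt$maximum), min_dispersion)
  new_dispersion_fit(rep(phi, nrow(counts)), "apl.common", "common",
                     aux = list(common_phi = phi), gene_ids = rownames(counts))
}

#' Trended APL dispersion estimator
#'
#' Bins genes by abundance (equal-occupancy bins of mean log normalized
#' count), maximizes a common APL within each bin, fits a local linear
#' regression (tricube weights) of log dispersion on bin abundance, and
#' assigns each gene its fitted trend value, clamped to the range of the bin
#' estimates so the trend never extrapolates beyond what was observed.
#'
#' @inheritParams ql_genewise
#' @param n_bins Number of equal-occupancy abundance bins.
#' @param span Local-regression span.
#' @return A \code{dispersion_fit}; \code{aux$trend} holds the per-bin
#'   abundance/dispersion pairs.
#' @export
apl_trended <- function(counts, groups, effective_sizes, n_bins = 20L,
                        span = 0.3, min_dispersion = .DEFAULT_PHI_FLOOR) {
  groups <- as.factor(groups)
  G <- nrow(counts)
  if (G < 2L * n_bins) stop("too few genes for ", n_bins, " abundance bins")
  a <- gene_abundance(counts, effective_sizes)
  # quantile-value bins: approximately equal occupancy, and tied abundances
  # always share a bin, so the fit is invariant to gene ordering
  brks <- unique(stats::quantile(a, seq(0, 1, length.out = n_bins + 1)))
  if (length(brks) < 3) stop("abundances too discrete for a trend fit")
  bins <- cut(a, brks, include.lowest = TRUE, labels = FALSE)
  n_bins <- length(brks) - 1L
  centers <- lphi_bin <- numeric(n_bins)
  for (b in seq_len(n_bins)) {
    idx <- which(bins == b)
    if (length(idx) == 0L) { centers[b] <- NA; lphi_bin[b] <- NA; next }
    centers[b] <- mean(a[idx])
    f <- function(lphi) mean(apl_group_vec(counts[idx, , drop = FALSE], groups,
                                           effective_sizes, exp(lphi)))
    lphi_bin[b] <- stats::optimize(f, log(.APL_PHI_RANGE), maximum = TRUE,
                                   tol = 1e-6)$maximum
  }
  ok <- !is.na(centers)
  centers <- centers[ok]; lphi_bin <- lphi_bin[ok]
  lo <- lo_fit(centers, lphi_bin, span)
  fitted <- stats::predict(lo, pmin(pmax(a, min(centers)), max(centers)))
  fitted <- pmin(pmax(fitted, min(lphi_bin)), max(lphi_bin))
  phi <- pmax(exp(fitted), min_dispersion)
  new_dispersion_fit(phi, "apl.trended", "trended",
                     aux = list(trend = data.frame(abundance = centers,
                                                   log_phi = lphi_bin)),
                     gene_ids = rownames(counts))
}

# Local linear regression with tricube weights; span widened as needed so
# every neighborhood has enough points for a degree-1 fit.
lo_fit <- function(x, y, span) {
  span <- max(span, 4.5 / length(x))
  stats::loess(y ~ x, span = span, degree = 1,
               control = stats::loess.control(surface = "direct"))
}

#' Tagwise APL dispersion estimator
#'
#' Shrinks each gene's APL-maximizing dispersion toward the common estimate of
#' its abundance neighborhood: per gene the objective
#' \code{APL_g(phi) + W * S_g(phi)} is maximized, where \code{S_g} is the mean
#' APL over the K genes nearest in abundance and \code{W} is the prior weight
#' in equivalent genes. By default \code{W} is set by the same
#' empirical-Bayes moment-matching rule as \code{\link{wqcml_tagwise}}.
#'
#' @inheritParams ql_genewise
#' @param prior_weight Shrinkage weight W (equivalent genes); \code{NULL}
#'   (default) applies the moment-matching rule.
#' @param k_neighbors Neighborhood size K (capped at a quarter of the genes).
#' @return A \code{dispersion_fit}.
#' @export
apl_tagwise <- function(counts, groups, effective_sizes, prior_weight = NULL,
                        k_neighbors = 50L,
                        min_dispersion = .DEFAULT_PHI_FLOOR) {
  stopifnot(is.null(prior_weight) || prior_weight >= 0)
  groups <- as.factor(groups)
  G <- nrow(counts)
  K <- max(1L, min(as.integer(k_neighbors), G %/% 4L))
  a <- gene_abundance(counts, effective_sizes)
  ord <- order(a)
  # APL curves for every gene on a log-phi grid (vectorized fits), from which
  # neighborhood means come as centered rolling windows over the abundance
  # ordering; the grid locates a bracket and the exact windowed objective is
  # then maximized inside it
  grid <- seq(log(.APL_PHI_RANGE[1]), log(.APL_PHI_RANGE[2]), length.out = 31)
  curves <- matrix(vapply(grid, function(lp)
    apl_group_vec(counts, groups, effective_sizes, exp(lp)), numeric(G)),
    nrow = G)
  if (is.null(prior_weight))
    prior_weight <- eb_prior_weight(curves, grid,
                                    max(ncol(counts) - nlevels(groups), 1L))
  curves_ord <- curves[ord, , drop = FALSE]
  half <- K %/% 2L
  csum <- apply(rbind(0, curves_ord), 2, cumsum)   # (G+1) x grid
  ng <- length(grid)
  S <- matrix(0, G, ng)            # S[g, ] in original gene order
  for (k in seq_len(G)) {
    loi <- max(1L, k - half); hii <- min(G, loi + K - 1L)
    loi <- max(1L, hii - K + 1L)
    S[ord[k], ] <- (csum[hii + 1L, ] - csum[loi, ]) / (hii - loi + 1L)
  }
  if (G <= 200L) {
    # exact windowed objective, per gene, over the full range
    windows <- vector("list", G)
    for (k in seq_len(G)) {
      loi <- max(1L, k - half); hii <- min(G, loi + K - 1L)
      loi <- max(1L, hii - K + 1L)
      windows[[ord[k]]] <- ord[loi:hii]
    }
    phi <- numeric(G)
    for (g in seq_len(G)) {
      nb <- windows[[g]]
      f <- function(lphi) {
        av <- apl_group_vec(counts[c(g, nb), , drop = FALSE], groups,
                            effective_sizes, exp(lphi))
        av[1] + prior_weight * mean(av[-1])
      }
      phi[g] <- exp(stats::optimize(f, range(grid), maximum = TRUE,
                                    tol = 1e-5)$maximum)
    }
  } else {
    # bracket each gene's maximum on the grid, approximate the (smooth, slowly
    # varying) neighborhood term by its local quadratic through the bracketing
    # grid points, and refine all genes at once by golden section with the
    # gene's own APL evaluated exactly
    obj_grid <- curves + prior_weight * S
    i <- max.col(obj_grid, ties.method = "first")
    i <- pmin(pmax(i, 2L), ng - 1L)
    h <- grid[2] - grid[1]
    s0 <- S[cbind(seq_len(G), i - 1L)]
    s1 <- S[cbind(seq_len(G), i)]
    s2 <- S[cbind(seq_len(G), i + 1L)]
    t1 <- grid[i]
    qa <- (s0 - 2 * s1 + s2) / (2 * h^2)
    qb <- (s2 - s0) / (2 * h)
    f <- function(lphi) {
      apl_group_vec(counts, groups, effective_sizes, exp(lphi)) +
        prior_weight * (s1 + qb * (lphi - t1) + qa * (lphi - t1)^2)
    }
    lphi <- golden_max_vec(f, grid[i - 1L], grid[i + 1L], tol = 1e-4)
    phi <- exp(lphi)
  }
  new_dispersion_fit(pmax(phi, min_dispersion), "apl.tagwise", "tagwise",
                     aux = list(prior_weight = prior_weight, k_neighbors = K),
                     gene_ids = rownames(counts))
}
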