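# Method-of-moments dispersion estimation on directly normalized counts, in
# genewise, trended (local regression of raw variance on mean) and maximum
# (elementwise max of genewise and trended) variants.

# Shared moment machinery: normalized counts x_gj = y_gj / c_j, per-gene mean
# q, pooled within-group sample variance w, sampling-noise bias term
# z = q * mean(1/c_j) (which cancels the Poisson part of w so that the raw
# variance v = w - z is ~0 for non-overdispersed genes), and phi = v+ / q^2.
mom_raw <- function(counts, groups, norm_factors) {
  groups <- as.factor(groups)
  df <- ncol(counts) - nlevels(groups)
  if (df <= 0) stop("method-of-moments needs a group with >= 2 libraries")
  x <- sweep(counts, 2, norm_factors, "/")
  q <- rowMeans(x)
  ss <- 0
  for (lev in levels(groups)) {
    idx <- which(groups == lev)
    xg <- x[, idx, drop = FALSE]
    ss <- ss + rowSums((xg - rowMeans(xg))^2)
  }
  w <- ss / df
  z <- q * mean(1 / norm_factors)
  v <- w - z
  list(q = q, w = w, z = z, v = v, df = df)
}

#' Genewise method-of-moments dispersion estimator
#'
#' Per gene, the raw variance is the pooled within-group sample variance of
#' the normalized counts minus a bias term that removes the Poisson sampling
#' noise; the dispersion is the positive part of the raw variance divided by
#' the squared normalized mean.
#'
#' @param counts Genes x libraries count matrix.
#' @param groups Group labels.
#' @param norm_factors Per-library normalization factors.
#' @param min_dispersion Floor applied to the estimates.
#' @return A \code{dispersion_fit}; \code{aux} carries the per-gene moments
#'   \code{q} and \code{v} used by the trended variant.
#' @export
mom_genewise <- function(counts, groups, norm_factors,
                         min_dispersion = .DEFAULT_PHI_FLOOR) {
  m <- mom_raw(counts, groups, norm_factors)
  bad <- m$q <= 0
  phi <- rep(min_dispersion, nrow(counts))
  phi[!bad] <- pmax(pmax(m$v[!bad], 0) / m$q[!bad]^2, min_dispersion)
  if (any(bad)) warning(sum(bad), " gene(s) with zero normalized mean floored")
  new_dispersion_fit(phi, "mom.genewise", "none",
                     aux = list(q = m$q, v = m$v, df = m$df, floored = bad | m$v <= 0),
                     gene_ids = rownames(counts))
}

#' Trended method-of-moments dispersion estimator
#'
#' Local regression of the log raw variance on the log normalized mean
#' (genes with non-positive raw variance are excluded from the fit); each
#' gene's dispersion comes from its fitted raw variance at its own mean.
#' Fitting on the log scale keeps every fitted variance positive.
#'
#' @inheritParams mom_genewise
#' @param span Local-regression span.
#' @return A \code{dispersion_fit}.
#' @export
mom_trended <- function(counts, groups, norm_factors, span = 0.3,
                        min_dispersion = .DEFAULT_PHI_FLOOR) {
  m <- mom_raw(counts, groups, norm_factors)
  use <- m$v > 0 & m$q > 0
  if (sum(use) < 20L)
    stop("too few genes with positive raw variance for a trend fit")
  lo <- lo_fit(log(m$q[use]), log(m$v[use]), span)
  lq <- log(pmax(m$q, min(m$q[use])))
  lq <- pmin(pmax(lq, min(log(m$q[use]))), max(log(m$q[use])))
  vhat <- exp(stats::predict(lo, lq))
  phi <- pmax(vhat / m$q^2, min_dispersion)
  phi[m$q <= 0] <- min_dispersion
  new_dispersion_fit(phi, "mom.trended", "trended",
                     aux = list(q = m$q, v = m$v, vhat = vhat),
                     gene_ids = rownames(counts))
}

#' Maximum method-of-moments dispersion estimator
#'
#' Elementwise maximum of the genewise and trended estimates: conservative,
#' allowing overestimation of the dispersions but guarding against the
#' underestimation that inflates false positives.
#'
#' @inheritParams mom_trended
#' @return A \code{dispersion_fit}.
#' @export
mom_maximum <- function(counts, groups, norm_factors, span = 0.3,
                        min_dispersion = .DEFAULT_PHI_FLOOR) {
  gw <- mom_genewise(counts, groups, norm_factors, min_dispersion)
  tr <- mom_trended(counts, groups, norm_factors, span, min_dispersion)
  new_dispersion_fit(pmax(gw$phi, tr$phi), "mom.maximum", "maximum",
                     aux = list(genewise = gw$phi, trended = tr$phi),
                     gene_ids = rownames(counts))
}
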