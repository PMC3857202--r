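# Library normalization: median-of-ratios factors, conversion to adjusted
# (effective) library sizes, and NB quantile adjustment to a common size for
# the conditional-likelihood estimators.

#' Median-of-ratios normalization factors
#'
#' For each library, every count is divided by the across-library geometric
#' mean of its gene, and the library's factor is the median of these ratios.
#' Genes whose geometric mean is zero (any zero count) are skipped, which
#' avoids division by zero.
#'
#' @param counts Genes x libraries count matrix.
#' @return Positive numeric vector of per-library factors \code{c_j}.
#' @export
median_of_ratios <- function(counts) {
  counts <- as.matrix(counts)
  geo <- exp(rowMeans(log(counts)))  # zero counts give geo = 0 via log -> -Inf
  usable <- is.finite(geo) & geo > 0
  if (!any(usable))
    stop("no gene with all-positive counts; cannot normalize")
  ratios <- counts[usable, , drop = FALSE] / geo[usable]
  apply(ratios, 2, stats::median)
}

#' Adjusted (effective) library sizes
#'
#' Converts normalization factors to effective library sizes by rescaling the
#' factors so that the total sequencing depth is conserved:
#' \code{L_j = c_j * sum(N_j) / sum(c_j)}. When all factors are equal every
#' library gets the mean library size.
#'
#' @param counts Count matrix (used for the observed library sizes
#'   \code{N_j = colSums(counts)}).
#' @param norm_factors Positive per-library factors.
#' @return Positive numeric vector of effective sizes summing to
#'   \code{sum(counts)}.
#' @export
adjusted_lib_sizes <- function(counts, norm_factors) {
  if (any(norm_factors <= 0)) stop("normalization factors must be positive")
  N <- colSums(as.matrix(counts))
  norm_factors * sum(N) / sum(norm_factors)
}

#' Quantile-adjust counts to a common library size
#'
#' Maps each count through NB distribution functions so that all libraries
#' behave as if sequenced to the same depth (the geometric mean of the
#' effective sizes): for gene g and library j with fitted mean proportional to
#' its effective size, the count's mid-distribution probability
#' \code{(F_j(y-1) + F_j(y))/2} is pushed through the inverse cdf at the
#' common size. The mapping is deterministic, monotone within a library, and
#' an exact no-op when all effective sizes are already equal.
#'
#' @param counts Genes x libraries count matrix.
#' @param effective_sizes Per-library effective sizes.
#' @param phi Dispersion used for the NB cdfs: a scalar or per-gene vector.
#' @return List with \code{values} (pseudo-count matrix) and
#'   \code{common_size} (the equalized library size).
#' @export
quantile_adjust <- function(counts, effective_sizes, phi) {
  counts <- as.matrix(counts)
  G <- nrow(counts); J <- ncol(counts)
  L <- rep_len(effective_sizes, J)
  phi <- rep_len(phi, G)
  if (any(phi < 0)) stop("phi must be non-negative")
  Lstar <- exp(mean(log(L)))
  if (max(abs(L / Lstar - 1)) < 1e-12)
    return(list(values = counts, common_size = Lstar))
  p_g <- rowSums(counts) / sum(L)            # per-gene rate per unit size
  pseudo <- matrix(0, G, J, dimnames = dimnames(counts))
  for (j in seq_len(J)) {
    mu_j <- pmax(p_g * L[j], 1e-10)
    mu_s <- pmax(p_g * Lstar, 1e-10)
    y <- counts[, j]
    pois <- phi < .PHI_POISSON
    p_hi <- p_lo <- numeric(G)
    if (any(pois)) {
      p_hi[pois] <- stats::ppois(y[pois], mu_j[pois])
      p_lo[pois] <- stats::ppois(y[pois] - 1, mu_j[pois])
    }
    if (any(!pois)) {
      r <- 1 / phi[!pois]
      p_hi[!pois] <- stats::pnbinom(y[!pois], size = r, mu = mu_j[!pois])
      p_lo[!pois] <- stats::pnbinom(y[!pois] - 1, size = r, mu = mu_j[!pois])
    }
    p_mid <- pmin(pmax((p_lo + p_hi) / 2, 1e-300), 1 - 1e-12)
    q <- numeric(G)
    if (any(pois)) q[pois] <- stats::qpois(p_mid[pois], mu_s[pois])
    if (any(!pois)) q[!pois] <- stats::qnbinom(p_mid[!pois], size = 1 / phi[!pois],
                                               mu = mu_s[!pois])
    pseudo[, j] <- q
  }
  list(values = pseudo, common_size = Lstar)
}
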