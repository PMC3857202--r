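# Dispersion parameterization used package-wide: Var(Y) = mu + phi * mu^2.
# Internally the size parameter r = 1/phi is passed to the d/p/q/rnbinom family.
# Below this threshold the NB pmf is numerically indistinguishable from the
# Poisson limit and log-gamma cancellation dominates, so we switch families.
.PHI_POISSON <- 1e-10

#' Negative binomial log probability mass function
#'
#' Log pmf of the NB(mu, phi) distribution with mean \code{mu} and dispersion
#' \code{phi}, parameterized so that the variance is \code{mu + phi * mu^2}.
#' For \code{phi} below \code{1e-10} the Poisson(\code{mu}) log pmf is returned,
#' which is the phi -> 0 limit of the NB family.
#'
#' @param y Non-negative integer count (vectorized).
#' @param mu Positive mean (vectorized).
#' @param phi Non-negative dispersion (scalar or vectorized).
#' @return Log probability mass, same length as the recycled arguments.
#' @examples
#' nb_log_pmf(0, mu = 1, phi = 0)     # log(exp(-1)) = -1
#' nb_log_pmf(3, mu = 2, phi = 0.5)
#' @export
nb_log_pmf <- function(y, mu, phi) {
  if (any(y < 0) || any(y != floor(y)))
    stop("'y' must contain non-negative integers")
  if (any(mu <= 0)) stop("'mu' must be positive")
  if (any(phi < 0)) stop("'phi' must be non-negative")
  n <- max(length(y), length(mu), length(phi))
  y <- rep_len(y, n); mu <- rep_len(mu, n); phi <- rep_len(phi, n)
  out <- numeric(n)
  pois <- phi < .PHI_POISSON
  if (any(pois)) out[pois] <- stats::dpois(y[pois], mu[pois], log = TRUE)
  if (any(!pois))
    out[!pois] <- stats::dnbinom(y[!pois], size = 1 / phi[!pois],
                                 mu = mu[!pois], log = TRUE)
  out
}

#' Negative binomial log likelihood
#'
#' Sum of NB log pmf terms for a vector of counts with per-observation means
#' and a shared dispersion.
#'
#' @param counts Non-negative integer vector.
#' @param mus Positive means, same length as \code{counts}.
#' @param phi Non-negative dispersion (scalar).
#' @return Scalar log likelihood.
#' @export
nb_loglik <- function(counts, mus, phi) {
  if (length(counts) != length(mus))
    stop("'counts' and 'mus' must have equal length")
  sum(nb_log_pmf(counts, mus, phi))
}

#' Negative binomial mean and variance
#'
#' @param mu Positive mean.
#' @param phi Non-negative dispersion.
#' @return Named numeric vector \code{c(mean, variance)} with
#'   variance \code{mu + phi * mu^2}.
#' @export
nb_moments <- function(mu, phi) {
  if (any(mu <= 0)) stop("'mu' must be positive")
  if (any(phi < 0)) stop("'phi' must be non-negative")
  c(mean = mu, variance = mu + phi * mu^2)
}

# Random NB draws in the (mu, phi) parameterization; phi = 0 falls back to
# Poisson.
rnb <- function(n, mu, phi) {
  if (length(phi) == 1L && phi < .PHI_POISSON) return(stats::rpois(n, mu))
  phi <- rep_len(phi, n)
  out <- integer(n)
  pois <- phi < .PHI_POISSON
  mu <- rep_len(mu, n)
  if (any(pois)) out[pois] <- stats::rpois(sum(pois), mu[pois])
  if (any(!pois)) out[!pois] <- stats::rnbinom(sum(!pois), size = 1 / phi[!pois],
                                               mu = mu[!pois])
  out
}

# Unit NB deviance summed over observations: 2 * [loglik(saturated) - loglik(mu)].
# Handles y = 0 (the y*log(y/mu) term vanishes).
nb_deviance <- function(y, mu, phi) {
  yl <- ifelse(y > 0, y * log(y / mu), 0)
  if (phi < .PHI_POISSON) {
    2 * sum(yl - (y - mu))
  } else {
    r <- 1 / phi
    2 * sum(yl - (y + r) * log((y + r) / (mu + r)))
  }
}

# Newton solver for the per-group NB mean MLE at fixed phi with library-size
# offsets: mu_j = lambda * L_j.  Vectorized across genes: 'y' is a G x n matrix
# of one group's counts, 'sizes' its effective library sizes.  Solves, per gene,
#   d/d(log lambda) loglik = sum_j (y_j - lambda L_j) / (1 + phi lambda L_j) = 0.
# At phi = 0 the closed form lambda = sum(y)/sum(L) is exact and used as start.
fit_group_lambda <- function(y, sizes, phi, tol = 1e-8, maxit = 50L) {
  y <- rbind(y)  # keep matrix form for a single gene
  L <- rep_len(sizes, ncol(y))
  lam <- pmax(rowSums(y) / sum(L), 1e-8)
  if (all(phi < .PHI_POISSON)) return(lam)
  phi <- rep_len(phi, nrow(y))
  for (it in seq_len(maxit)) {
    muL <- outer(lam, L)                       # G x n matrix of lambda*L_j
    den <- 1 + phi * muL
    f <- rowSums((y - muL) / den)              # score wrt log lambda, up to >0 factor? no:
    # score wrt lambda is f/lam; work in log scale: g = f (score * lambda)
    # derivative wrt log lambda: sum_j [ -(muL)(1+phi y_j) / den^2 ] * ... use numeric-safe
    dg <- -rowSums(muL * (1 + phi * y) / den^2)
    step <- f / dg
    step <- pmax(pmin(step, 2), -2)            # damp large Newton steps in log space
    lam_new <- lam * exp(-step)
    if (max(abs(log(lam_new / lam))) < tol) { lam <- lam_new; break }
    lam <- lam_new
  }
  pmax(lam, 1e-12)
}

# Fitted means for a two-level group design at fixed per-gene phi.
# Returns a G x J matrix of mu_gj = lambda_{g,k(j)} * L_j.
fit_group_means <- function(counts, groups, sizes, phi) {
  groups <- as.factor(groups)
  mu <- matrix(0, nrow(counts), ncol(counts))
  for (lev in levels(groups)) {
    idx <- which(groups == lev)
    lam <- fit_group_lambda(counts[, idx, drop = FALSE], sizes[idx], phi)
    mu[, idx] <- outer(lam, sizes[idx])
  }
  dimnames(mu) <- dimnames(counts)
  mu
}

# Validate a genes x libraries count matrix plus group labels; used by loaders
# and estimator entry points.
validate_counts <- function(counts, groups, warn_zero_rows = TRUE) {
  counts <- as.matrix(counts)
  if (!is.numeric(counts)) stop("counts must be numeric")
  if (any(!is.finite(counts)) || any(counts < 0) || any(counts != floor(counts)))
    stop("counts must be finite non-negative integers")
  groups <- as.factor(groups)
  if (length(groups) != ncol(counts))
    stop("'groups' must have one label per library (column)")
  if (any(table(groups) < 1L)) stop("each group needs at least one library")
  if (warn_zero_rows && any(rowSums(counts) == 0))
    warning("some genes have all-zero counts; estimators may floor them")
  storage.mode(counts) <- "double"
  list(counts = counts, groups = groups)
}

#' Read a count matrix from TSV
#'
#' Tab-separated file with a \code{gene_id} first column and one column per
#' library; the header row carries the library labels. Group labels are always
#' supplied separately, never inferred from headers.
#'
#' @param path File path.
#' @return Integer matrix with gene ids as row names.
#' @export
read_counts <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (colnames(df)[1] != "gene_id") stop("first column must be 'gene_id'")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene_id
  if (any(!is.finite(m)) || any(m < 0) || any(m != floor(m)))
    stop("counts must be finite non-negative integers")
  if (any(rowSums(m) == 0))
    warning("loaded counts contain all-zero genes")
  m
}

#' Write a count matrix to TSV
#'
#' @param counts Matrix with gene ids as row names.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_counts <- function(counts, path) {
  df <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
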