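# Genewise quasi-likelihood dispersion estimation: alternate NB mean MLEs at
# fixed phi with a quasi-likelihood moment equation for phi.

# Vectorized solver of the per-gene QL moment equation
#   sum_j (y_gj - mu_gj)^2 / (mu_gj + phi mu_gj^2) = df
# The left side is strictly decreasing in phi, so a positive root exists iff
# the Pearson statistic at phi = 0 exceeds df; otherwise the gene is floored.
ql_phi_solve <- function(counts, mu, df, floor, cap = 100) {
  resid2 <- (counts - mu)^2
  pearson0 <- rowSums(resid2 / mu)
  has_root <- pearson0 > df
  phi <- rep(floor, nrow(counts))
  if (any(has_root)) {
    lo <- rep(log(max(floor, 1e-8)), sum(has_root))
    hi <- rep(log(cap), sum(has_root))
    r2 <- resid2[has_root, , drop = FALSE]
    m <- mu[has_root, , drop = FALSE]
    stat <- function(lphi) rowSums(r2 / (m + exp(lphi) * m^2))
    hi_ok <- stat(hi) < df          # genes whose root is below the cap
    for (it in 1:50) {
      mid <- (lo + hi) / 2
      s <- stat(mid)
      below <- s > df               # root is to the right
      lo[below] <- mid[below]
      hi[!below] <- mid[!below]
    }
    root <- exp((lo + hi) / 2)
    root[!hi_ok] <- cap
    phi[has_root] <- pmax(root, floor)
  }
  list(phi = phi, floored = !has_root)
}

#' Genewise quasi-likelihood dispersion estimator
#'
#' For each gene, alternates (a) NB maximum-likelihood estimation of the group
#' means at the current dispersion and (b) solving the quasi-likelihood moment
#' equation (generalized Pearson statistic equals its residual degrees of
#' freedom) for the dispersion. Genes whose Pearson statistic never exceeds
#' the residual df have no positive root and are set to the common floor,
#' which produces the characteristic vertical bar of minimum-value estimates.
#'
#' @param counts Genes x libraries count matrix.
#' @param groups Group labels (two levels).
#' @param effective_sizes Per-library effective sizes used as offsets.
#' @param min_dispersion Floor for genes without a positive root.
#' @param max_iter,tol Alternation control.
#' @return A \code{dispersion_fit} with \code{aux$floored} flagging
#'   floor-assigned genes.
#' @export
ql_genewise <- function(counts, groups, effective_sizes,
                        min_dispersion = .DEFAULT_PHI_FLOOR,
                        max_iter = 20L, tol = 1e-6) {
  groups <- as.factor(groups)
  df <- ncol(counts) - nlevels(groups)
  if (df <= 0) {
    warning("no residual degrees of freedom; all estimates floored")
    return(new_dispersion_fit(rep(min_dispersion, nrow(counts)), "ql.genewise",
                              "none", aux = list(floored = rep(TRUE, nrow(counts))),
                              gene_ids = rownames(counts)))
  }
  phi <- rep(min_dispersion, nrow(counts))
  floored <- rep(TRUE, nrow(counts))
  for (it in seq_len(max_iter)) {
    mu <- fit_group_means(counts, groups, effective_sizes, phi)
    sol <- ql_phi_solve(counts, mu, df, min_dispersion)
    delta <- max(abs(log(pmax(sol$phi, 1e-12)) - log(pmax(phi, 1e-12))))
    phi <- sol$phi; floored <- sol$floored
    if (delta < tol) break
  }
  new_dispersion_fit(phi, "ql.genewise", "none",
                     aux = list(floored = floored, iterations = it),
                     gene_ids = rownames(counts))
}
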