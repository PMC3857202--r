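# Estimator registry and the dispersion_fit S3 class shared by all ten
# estimators.  The shrinkage taxonomy follows the study's grouping:
#   none     - each gene on its own (ql.genewise, mom.genewise)
#   common   - one value for all genes (qcml.common, apl.common)
#   trended  - a smooth function of abundance (apl.trended, mom.trended)
#   tagwise  - moderate shrinkage toward a common value, neighborhood or prior
#              (wqcml.tagwise, apl.tagwise, dss)
#   maximum  - elementwise max of genewise and trended (mom.maximum)

.DEFAULT_PHI_FLOOR <- 1e-4

#' Registered dispersion estimators
#'
#' @return Named character vector: names are method identifiers accepted by
#'   \code{\link{estimate_dispersions}}, values their shrinkage class.
#' @export
dispersion_methods <- function() {
  c(ql.genewise = "none", mom.genewise = "none",
    qcml.common = "common", apl.common = "common",
    apl.trended = "trended", mom.trended = "trended",
    wqcml.tagwise = "tagwise", apl.tagwise = "tagwise", dss = "tagwise",
    mom.maximum = "maximum")
}

new_dispersion_fit <- function(phi, method, shrinkage, aux = list(),
                               gene_ids = NULL) {
  phi <- as.numeric(phi)
  if (!is.null(gene_ids)) names(phi) <- gene_ids
  structure(list(phi = phi, method = method, shrinkage = shrinkage, aux = aux),
            class = "dispersion_fit")
}

#' Estimate per-gene NB dispersions
#'
#' Single entry point dispatching to the ten registered estimators. Counts are
#' normalized internally (median-of-ratios by default) and each estimator
#' receives the normalization representation it expects: effective library
#' sizes for the likelihood-based methods, raw factors for the
#' method-of-moments family.
#'
#' @param counts Genes x libraries integer count matrix.
#' @param groups Length-J group labels (two levels).
#' @param method One of \code{names(dispersion_methods())}.
#' @param normalization \code{"median_of_ratios"} or \code{"none"} (all
#'   factors 1).
#' @param ... Passed to the underlying estimator.
#' @return A \code{dispersion_fit}: per-gene estimates \code{phi}, the method
#'   and shrinkage labels, and method-specific diagnostics in \code{aux}.
#' @examples
#' sim <- generate_pseudo_dataset(simulation_config(n_genes = 200, seed = 1))
#' fit <- estimate_dispersions(sim$counts, sim$groups, "mom.genewise")
#' summary(fit)
#' @export
estimate_dispersions <- function(counts, groups,
                                 method = names(dispersion_methods()),
                                 normalization = c("median_of_ratios", "none"),
                                 ...) {
  method <- match.arg(method)
  normalization <- match.arg(normalization)
  v <- validate_counts(counts, groups, warn_zero_rows = FALSE)
  counts <- v$counts; groups <- v$groups
  cf <- if (normalization == "none") rep(1, ncol(counts)) else
    median_of_ratios(counts)
  sizes <- adjusted_lib_sizes(counts, cf)
  fit <- switch(method,
    ql.genewise   = ql_genewise(counts, groups, sizes, ...),
    mom.genewise  = mom_genewise(counts, groups, cf, ...),
    qcml.common   = qcml_common(counts, groups, sizes, ...),
    apl.common    = apl_common(counts, groups, sizes, ...),
    apl.trended   = apl_trended(counts, groups, sizes, ...),
    mom.trended   = mom_trended(counts, groups, cf, ...),
    wqcml.tagwise = wqcml_tagwise(counts, groups, sizes, ...),
    apl.tagwise   = apl_tagwise(counts, groups, sizes, ...),
    dss           = dss(counts, groups, cf, ...),
    mom.maximum   = mom_maximum(counts, groups, cf, ...))
  fit$aux$norm_factors <- cf
  fit$aux$effective_sizes <- sizes
  fit
}

#' @export
print.dispersion_fit <- function(x, ...) {
  cat("Dispersion fit:", x$method, "(shrinkage:", paste0(x$shrinkage, ")"), "\n")
  cat("  genes:", length(x$phi), "\n")
  qs <- stats::quantile(x$phi, c(0, 0.25, 0.5, 0.75, 1))
  cat("  phi quartiles:", paste(signif(qs, 3), collapse = "  "), "\n")
  invisible(x)
}

#' @export
summary.dispersion_fit <- function(object, ...) {
  out <- list(method = object$method, shrinkage = object$shrinkage,
              n_genes = length(object$phi),
              quartiles = stats::quantile(object$phi, c(0, .25, .5, .75, 1)),
              n_floored = sum(object$phi <= .DEFAULT_PHI_FLOOR * (1 + 1e-8)))
  class(out) <- "summary.dispersion_fit"
  out
}

#' @export
print.summary.dispersion_fit <- function(x, ...) {
  cat("Method:", x$method, "  shrinkage:", x$shrinkage, "\n")
  cat("Genes:", x$n_genes, "  at floor:", x$n_floored, "\n")
  print(signif(x$quartiles, 4))
  invisible(x)
}

#' @export
coef.dispersion_fit <- function(object, ...) object$phi

#' @export
plot.dispersion_fit <- function(x, abundance = NULL, ...) {
  if (is.null(abundance)) abundance <- seq_along(x$phi)
  graphics::plot(abundance, log(x$phi),
                 xlab = if (is.null(names(abundance))) "gene index" else
                   "abundance",
                 ylab = "log dispersion",
                 main = paste(x$method, "dispersion estimates"),
                 pch = 16, cex = 0.4, col = grDevices::grey(0.3, 0.5), ...)
  invisible(x)
}

#' Write / read dispersion estimates as TSV
#'
#' Columns: \code{gene_id, phi_hat, method, shrinkage}.
#'
#' @param fit A \code{dispersion_fit}.
#' @param path File path.
#' @return \code{write_dispersion_fit}: the path, invisibly;
#'   \code{read_dispersion_fit}: a \code{dispersion_fit}.
#' @export
write_dispersion_fit <- function(fit, path) {
  ids <- names(fit$phi)
  if (is.null(ids)) ids <- sprintf("gene%05d", seq_along(fit$phi))
  utils::write.table(
    data.frame(gene_id = ids, phi_hat = fit$phi, method = fit$method,
               shrinkage = fit$shrinkage),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dispersion_fit
#' @export
read_dispersion_fit <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  new_dispersion_fit(df$phi_hat, df$method[1], df$shrinkage[1],
                     gene_ids = df$gene_id)
}

# Empirical-Bayes moment matching for the tagwise shrinkage weight (in
# equivalent genes): the between-gene variance of the genewise log-dispersion
# maximizers, minus the approximate per-gene estimation variance 2/df, leaves
# the true between-gene spread tau^2; the prior weight equates the prior's
# precision with 1/tau^2, i.e. W = (2/df)/tau^2.  Wide true spread => weak
# shrinkage, tight spread => strong shrinkage.
eb_prior_weight <- function(curve_mat, lgrid, df, fallback = 10) {
  i <- max.col(curve_mat, ties.method = "first")
  interior <- i > 1L & i < length(lgrid)
  if (sum(interior) < 30L) return(fallback)
  V <- stats::var(lgrid[i[interior]])
  noise <- 2 / df
  tau2 <- max(V - noise, 0.01)
  min(noise / tau2, 100)
}

# Vectorized golden-section maximizer: f takes a vector of per-gene points and
# returns per-gene objective values; lo/hi are per-gene brackets around a
# unimodal maximum.
golden_max_vec <- function(f, lo, hi, tol = 1e-4, maxit = 60L) {
  gr <- (sqrt(5) - 1) / 2
  x1 <- hi - gr * (hi - lo); x2 <- lo + gr * (hi - lo)
  f1 <- f(x1); f2 <- f(x2)
  for (it in seq_len(maxit)) {
    if (max(hi - lo) < tol) break
    left <- f1 >= f2
    hi[left] <- x2[left]; x2[left] <- x1[left]; f2[left] <- f1[left]
    x1[left] <- hi[left] - gr * (hi[left] - lo[left])
    lo[!left] <- x1[!left]; x1[!left] <- x2[!left]; f1[!left] <- f2[!left]
    x2[!left] <- lo[!left] + gr * (hi[!left] - lo[!left])
    xe <- ifelse(left, x1, x2)
    fe <- f(xe)
    f1[left] <- fe[left]; f2[!left] <- fe[!left]
  }
  (lo + hi) / 2
}

# Abundance measure shared by the trend-based estimators: log mean normalized
# count at the common (geometric-mean) library size, with a small offset so
# low-count genes stay finite.
gene_abundance <- function(counts, sizes) {
  Lstar <- exp(mean(log(sizes)))
  log(rowSums(counts) / sum(sizes) * Lstar + 0.125)
}
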