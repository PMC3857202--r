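# Pseudo-dataset generator: samples (mean, dispersion) pairs from a pool,
# flags an exact fraction of genes as differentially expressed, draws their
# log fold changes in correlated blocks, and simulates NB counts with the
# pair-wise mean-dispersion coupling intact.

# Deterministic sub-stream seeds derived from one master seed, so that the
# gene-level truth (pool sample, DE flags, log fold changes) is unchanged when
# only the group sizes change.  Kept below 2^31 - 1.
derive_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 48271 + stage * 9973) %% 2147483629)
}

#' Draw a random correlation matrix uniformly
#'
#' C-vine construction (partial correlations drawn from symmetric Beta
#' distributions mapped to (-1, 1)) that yields a draw from the uniform
#' distribution over the space of d x d correlation matrices.
#'
#' @param d Dimension.
#' @return A d x d positive-definite correlation matrix.
#' @export
rcorr_matrix <- function(d) {
  if (d == 1L) return(matrix(1, 1, 1))
  P <- matrix(0, d, d)
  R <- diag(d)
  beta <- 1 + (d - 1) / 2
  for (k in seq_len(d - 1)) {
    beta <- beta - 1 / 2
    for (i in seq(k + 1, d)) {
      P[k, i] <- 2 * stats::rbeta(1, beta, beta) - 1
      p <- P[k, i]
      if (k > 1) for (l in seq(k - 1, 1))
        p <- p * sqrt((1 - P[l, i]^2) * (1 - P[l, k]^2)) + P[l, i] * P[l, k]
      R[k, i] <- p
      R[i, k] <- p
    }
  }
  R
}

#' Sample block-correlated log fold changes
#'
#' Log fold changes for the differentially expressed genes are drawn from a
#' multivariate normal with mean zero and a block-diagonal covariance: each
#' block is a random correlation matrix drawn uniformly over all correlation
#' matrices, so every marginal is standard normal while genes within a block
#' are correlated. \code{block_size = 1} gives i.i.d. standard normals.
#'
#' @param n_de Number of DE genes; must be a multiple of \code{block_size}.
#' @param block_size Genes per correlated block.
#' @param seed Optional integer seed; if \code{NULL} the current RNG stream is
#'   used.
#' @return Numeric vector of length \code{n_de}.
#' @export
sample_lfc_blocks <- function(n_de, block_size, seed = NULL) {
  if (n_de == 0L) return(numeric(0))
  if (n_de %% block_size != 0L)
    stop("'block_size' must divide 'n_de'")
  if (!is.null(seed)) set.seed(as.integer(seed))
  n_blocks <- n_de %/% block_size
  delta <- numeric(n_de)
  for (b in seq_len(n_blocks)) {
    idx <- ((b - 1L) * block_size + 1L):(b * block_size)
    if (block_size == 1L) {
      delta[idx] <- stats::rnorm(1)
    } else {
      R <- rcorr_matrix(block_size)
      delta[idx] <- drop(crossprod(chol(R), stats::rnorm(block_size)))
    }
  }
  delta
}

#' Simulation configuration
#'
#' Bundles the knobs of one simulated two-group experiment. The defaults are
#' the study conditions used throughout: 10,000 genes, exactly 20% of them
#' differentially expressed, with DE log fold changes drawn in 40 correlated
#' blocks of 50.
#'
#' @param pool A \code{param_pool} or a preset name
#'   (\code{"pickrell-like"}/\code{"hammer-like"}) resolved at generation time.
#' @param n_genes Number of simulated genes.
#' @param de_fraction Fraction of genes differentially expressed;
#'   \code{n_genes * de_fraction} must be an integer.
#' @param group_sizes Integer pair: libraries in group 1 and group 2.
#' @param block_size Genes per correlated LFC block (1 = independent LFCs).
#' @param seed Master seed; all sub-streams derive from it.
#' @return A \code{simulation_config} list.
#' @export
simulation_config <- function(pool = "pickrell-like", n_genes = 10000L,
                              de_fraction = 0.2, group_sizes = c(3L, 3L),
                              block_size = 50L, seed = 1L) {
  n_de <- n_genes * de_fraction
  if (abs(n_de - round(n_de)) > 1e-9)
    stop("n_genes * de_fraction must be an integer")
  n_de <- as.integer(round(n_de))
  if (n_de > 0L && n_de %% block_size != 0L)
    stop("block_size must divide the DE gene count (", n_de, ")")
  if (length(group_sizes) != 2L || any(group_sizes < 1L))
    stop("group_sizes must be two positive integers")
  structure(list(pool = pool, n_genes = as.integer(n_genes),
                 de_fraction = de_fraction,
                 group_sizes = as.integer(group_sizes),
                 block_size = as.integer(block_size),
                 n_blocks = if (n_de > 0L) n_de %/% block_size else 0L,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

resolve_pool <- function(pool, n_genes, seed) {
  if (inherits(pool, "param_pool")) return(pool)
  if (is.character(pool) && length(pool) == 1L)
    return(emulate_pool(pool, size = 2L * n_genes, seed = derive_seed(seed, 0L)))
  stop("'pool' must be a param_pool or a preset name")
}

#' Generate a pseudo-dataset with known truth
#'
#' Implements the simulation recipe: (1) sample \code{n_genes}
#' (mean, dispersion) pairs from the pool without replacement, keeping each
#' pair together so the empirical dispersion-mean relationship survives;
#' (2) flag exactly \code{n_genes * de_fraction} genes as DE; (3) draw DE log
#' fold changes in correlated blocks (zero for EE genes); (4) split each
#' baseline geometric mean symmetrically, \code{mu1 = m exp(+delta/2)},
#' \code{mu2 = m exp(-delta/2)}, so \code{m} stays the across-treatment
#' geometric mean; (5) draw each count from NB(mu, phi); (6) any gene whose
#' simulated counts are all zero keeps its (m, phi) pair and DE flag, has its
#' delta redrawn from the marginal (0 for EE genes), and its counts redrawn
#' until at least one read is present.
#'
#' @param config A \code{simulation_config}.
#' @return List with \code{counts} (integer matrix, genes x libraries),
#'   \code{groups} (factor of length J), and \code{truth} (data frame:
#'   \code{gene_id, m, phi, is_de, delta, mu1, mu2}).
#' @export
generate_pseudo_dataset <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  G <- config$n_genes
  pool <- resolve_pool(config$pool, G, config$seed)
  if (nrow(pool) < G)
    stop("pool has ", nrow(pool), " rows; need at least ", G)
  n_de <- as.integer(round(G * config$de_fraction))

  set.seed(derive_seed(config$seed, 1L))
  rows <- sample.int(nrow(pool), G)          # without replacement
  m <- pool$mean[rows]
  phi <- pool$dispersion[rows]

  set.seed(derive_seed(config$seed, 2L))
  is_de <- logical(G)
  if (n_de > 0L) is_de[sample.int(G, n_de)] <- TRUE

  delta <- numeric(G)
  if (n_de > 0L)
    delta[is_de] <- sample_lfc_blocks(n_de, config$block_size,
                                      seed = derive_seed(config$seed, 3L))

  mu1 <- m * exp(delta / 2)
  mu2 <- m * exp(-delta / 2)

  n1 <- config$group_sizes[1]; n2 <- config$group_sizes[2]
  J <- n1 + n2
  groups <- factor(rep(c(1L, 2L), c(n1, n2)), labels = c("1", "2"))

  set.seed(derive_seed(config$seed, 4L))
  mu_mat <- cbind(matrix(mu1, G, n1), matrix(mu2, G, n2))
  counts <- matrix(rnb(G * J, mu = as.vector(mu_mat), phi = rep(phi, J)), G, J)

  # all-zero redraw: keep (m, phi) and DE flag, redraw delta from its marginal
  zero <- which(rowSums(counts) == 0)
  guard <- 0L
  while (length(zero) > 0L && guard < 1000L) {
    for (g in zero) {
      if (is_de[g]) delta[g] <- stats::rnorm(1)
      mu1[g] <- m[g] * exp(delta[g] / 2)
      mu2[g] <- m[g] * exp(-delta[g] / 2)
      counts[g, ] <- rnb(J, mu = rep(c(mu1[g], mu2[g]), c(n1, n2)),
                         phi = phi[g])
    }
    zero <- zero[rowSums(counts[zero, , drop = FALSE]) == 0]
    guard <- guard + 1L
  }
  if (length(zero) > 0L)
    stop("redraw limit reached for ", length(zero), " gene(s)")

  gene_id <- sprintf("gene%05d", seq_len(G))
  rownames(counts) <- gene_id
  colnames(counts) <- paste0("grp", rep(c(1L, 2L), c(n1, n2)), "_lib",
                             c(seq_len(n1), seq_len(n2)))
  storage.mode(counts) <- "integer"
  truth <- data.frame(gene_id = gene_id, m = m, phi = phi, is_de = is_de,
                      delta = delta, mu1 = mu1, mu2 = mu2,
                      stringsAsFactors = FALSE)
  list(counts = counts, groups = groups, truth = truth, config = config)
}

#' The six study simulation settings
#'
#' Two pools crossed with three group-size layouts: pickrell-like with 3+3,
#' 3+15 and 9+9 libraries, and hammer-like with 3+3, 3+16 and 9+9, each with
#' 10,000 genes, 20% DE and 40 correlated blocks of 50.
#'
#' @param n_genes Gene count per dataset (default the full 10,000; smaller
#'   values scale the design down while keeping block structure intact when
#'   divisible by the block layout).
#' @param seed Master seed applied to every setting.
#' @return Named list of six \code{simulation_config} objects (I-VI).
#' @export
study_settings <- function(n_genes = 10000L, seed = 1L) {
  layout <- list(
    I   = list(pool = "pickrell-like", sizes = c(3L, 3L)),
    II  = list(pool = "pickrell-like", sizes = c(3L, 15L)),
    III = list(pool = "pickrell-like", sizes = c(9L, 9L)),
    IV  = list(pool = "hammer-like",   sizes = c(3L, 3L)),
    V   = list(pool = "hammer-like",   sizes = c(3L, 16L)),
    VI  = list(pool = "hammer-like",   sizes = c(9L, 9L))
  )
  lapply(layout, function(x)
    simulation_config(pool = x$pool, n_genes = n_genes, de_fraction = 0.2,
                      group_sizes = x$sizes, block_size = 50L, seed = seed))
}

#' Write / read a truth table as TSV
#'
#' Columns: \code{gene_id, m, phi, is_de, delta, mu1, mu2}.
#'
#' @param truth Truth data frame from \code{\link{generate_pseudo_dataset}}.
#' @param path File path.
#' @return \code{write_truth}: the path, invisibly. \code{read_truth}: the
#'   truth data frame.
#' @export
write_truth <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  df$is_de <- as.logical(df$is_de)
  df
}
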