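# Shared fixtures, all generated in code.

# Deterministic toy count matrix: 4 genes x 6 libraries, two groups of 3.
toy_counts <- function() {
  m <- matrix(c(1, 2, 3, 10, 20, 30,
                5, 6, 4, 5, 6, 4,
                12, 15, 9, 30, 28, 35,
                2, 0, 1, 3, 1, 2), nrow = 4, byrow = TRUE)
  rownames(m) <- paste0("g", 1:4)
  colnames(m) <- paste0("lib", 1:6)
  m
}

toy_groups <- function() factor(rep(c(1, 2), each = 3))

# Small simulated dataset cached per test file run.
small_sim <- local({
  cache <- NULL
  function(n_genes = 300, group_sizes = c(3, 3), preset = "pickrell-like",
           seed = 7) {
    key <- paste(n_genes, paste(group_sizes, collapse = "+"), preset, seed)
    if (!is.null(cache) && identical(cache$key, key)) return(cache$sim)
    sim <- generate_pseudo_dataset(simulation_config(
      pool = preset, n_genes = n_genes, de_fraction = 0.2,
      group_sizes = group_sizes, block_size = n_genes %/% 20L, seed = seed))
    cache <<- list(key = key, sim = sim)
    sim
  }
})

# Dataset with a single shared dispersion: pool with constant phi.
const_phi_pool <- function(phi, size = 4000, seed = 1, mean_log = 3,
                           mean_sd = 1.5) {
  set.seed(seed)
  nbdispbench:::new_param_pool(exp(rnorm(size, mean_log, mean_sd)),
                               rep(phi, size), "const")
}

const_phi_sim <- function(phi, n_genes = 500, group_sizes = c(5, 5),
                          seed = 1, de_fraction = 0) {
  cfg <- simulation_config(pool = const_phi_pool(phi, seed = seed + 100),
                           n_genes = n_genes, de_fraction = de_fraction,
                           group_sizes = group_sizes,
                           block_size = max(1L, n_genes %/% 20L), seed = seed)
  generate_pseudo_dataset(cfg)
}

# Independent brute-force NB log pmf written straight from the gamma-function
# formula (size r = 1/phi), used as an oracle only.
oracle_nb_log_pmf <- function(y, mu, phi) {
  r <- 1 / phi
  lgamma(y + r) - lgamma(r) - lfactorial(y) +
    r * log(r / (r + mu)) + y * log(mu / (r + mu))
}
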