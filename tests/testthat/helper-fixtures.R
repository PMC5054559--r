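# Shared fixtures, built in code at test time.

# small beta matrix with ids
make_beta <- function(values, sample_ids, cpg_ids) {
  matrix(values, nrow = length(sample_ids), ncol = length(cpg_ids),
         dimnames = list(sample_ids, cpg_ids))
}

# tiny cohort used by fast module tests
small_cohort <- function(seed = 11, n1 = 60, n2 = 40, n_cpgs = 400,
                         n_causal = 10, n_celltypes = 3, ...) {
  cfg <- simulation_config(
    n_samples_batch1 = n1, n_samples_batch2 = n2, n_cpgs = n_cpgs,
    n_causal = n_causal, n_celltypes = n_celltypes,
    dirichlet_concentration = c(4, 2, 1), seed = seed, ...)
  ref <- generate_reference_profiles(n_celltypes, n_cpgs, seed = seed)
  list(cfg = cfg, ref = ref, cohort = generate_cohort(cfg, ref))
}

# brute-force Benjamini-Hochberg step-up definition:
# q_(i) = min(1, min_{j >= i} m * p_(j) / j), mapped back to input order
bh_brute_force <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) q[i] <- min(1, min(m * ps[i:m] / (i:m)))
  out <- numeric(m)
  out[o] <- q
  out
}

# all simplex grid points (step `step`) for K cell types, sum <= 1
simplex_grid <- function(K, step = 0.01) {
  g <- seq(0, 1, by = step)
  grid <- as.matrix(do.call(expand.grid, rep(list(g), K)))
  grid[rowSums(grid) <= 1 + 1e-12, , drop = FALSE]
}

# minimal evaluation object for report-level tests
fake_evaluation <- function(r_squared, pi_half_width, n = 100,
                            ga_definition = NA_character_) {
  structure(list(ga_definition = ga_definition, n = n, n_dropped = 0,
                 r_squared = r_squared, pi_half_width = pi_half_width,
                 slope = 1, intercept = 0, sigma = pi_half_width / 1.96),
            class = "ga_evaluation")
}

# random id set of a given size from a universe
id_set <- function(n, universe) sample(universe, n)

# one Dirichlet draw (test-local copy, independent of the package internals)
rdirichlet_test <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}
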