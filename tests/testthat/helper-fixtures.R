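# small designs and cached fits shared across test files

tiny_design <- function() {
  fc_design(n_blocks = 2, block_length = 3,
            traits = c(1, 2, 3, 1, 2, 3),
            keying = c(1, 1, -1, 1, -1, 1))
}

one_block_design <- function(keying = c(1, 1, 1)) {
  fc_design(n_blocks = 1, block_length = 3, traits = c(1, 2, 3),
            keying = keying, n_traits = 3)
}

# memoised small fits so several test files can share one MCMC run
.fit_cache <- new.env(parent = emptyenv())

small_sim <- function(seed = 42) {
  key <- paste0("sim", seed)
  if (is.null(.fit_cache[[key]])) {
    cfg <- sim_config(n_b = 3, K = 4, J = 20, d = 5)
    .fit_cache[[key]] <- simulate_mfc(cfg, seed = seed)
  }
  .fit_cache[[key]]
}

small_fit <- function(impl, seed = 42) {
  key <- paste0(impl, seed)
  if (is.null(.fit_cache[[key]])) {
    sim <- small_sim(seed)
    .fit_cache[[key]] <- fit_mfc(sim$rankings, sim$design, impl = impl,
                                 chains = 2, iter = 300, seed = seed)
  }
  .fit_cache[[key]]
}

# brute-force ranking probability by Monte Carlo simulation of utilities
mc_ranking_freqs <- function(params, theta, n_draws, seed) {
  theta_rep <- matrix(theta, n_draws, length(theta), byrow = TRUE)
  rk <- simulate_rankings(params$design, params, theta_rep, rng_seed = seed)
  m <- as.matrix(rk[, -1])
  table(apply(m, 1, paste, collapse = "")) / nrow(m)
}
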