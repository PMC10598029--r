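# Shared fixtures, all generated in code.

# small genome for fast simulator tests
small_config <- function(...) {
  sim_config(n_chrom = 4, bins_per_arm = 8, n_normals = 3, ...)
}

# panel of normals for a given genome configuration
make_pon <- function(cfg = small_config(), n = 3, seed = 9000) {
  normals <- lapply(seq_len(n), function(j)
    simulate_bin_counts(NULL, 0, cfg, seed = seed + j))
  normal_reference(normals)
}

# direct emission-level copy-number profile: a gain block, a loss block,
# diploid elsewhere, Gaussian noise around the mixture means
sim_log2_profile <- function(tfx, n_bins = 400, frac_gain = 0.2,
                             frac_loss = 0.1, sigma = 0.05, seed = 1) {
  set.seed(seed)
  states <- rep(2L, n_bins)
  n_gain <- round(frac_gain * n_bins)
  n_loss <- round(frac_loss * n_bins)
  states[seq_len(n_gain)] <- 3L
  states[n_gain + seq_len(n_loss)] <- 1L
  x <- stats::rnorm(n_bins, expected_log2(tfx, states), sigma)
  list(x = x, states = states)
}

# brute-force joint-probability maximization over all state paths; the
# independent oracle for Viterbi (and total likelihood via summation)
brute_force_hmm <- function(x, tfx, sigma, states = 0:4, p_stay = 0.99,
                            penalty = 2) {
  k <- length(states); n <- length(x)
  mu <- expected_log2(tfx, states)
  A <- plasmatrack:::.hmm_transitions(states, p_stay, penalty)
  pi0 <- plasmatrack:::.hmm_init(states, penalty)
  paths <- as.matrix(expand.grid(rep(list(seq_len(k)), n)))
  logp <- apply(paths, 1, function(p) {
    lp <- log(pi0[p[1]]) + stats::dnorm(x[1], mu[p[1]], sigma, log = TRUE)
    for (t in 2:n)
      lp <- lp + log(A[p[t - 1], p[t]]) +
        stats::dnorm(x[t], mu[p[t]], sigma, log = TRUE)
    lp
  })
  best <- which.max(logp)
  list(path = states[paths[best, ]],
       loglik = log(sum(exp(logp - max(logp)))) + max(logp))
}
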