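# light sampler settings used across tests: 2 chains, short adaptation, a
# moderate acceptance target (the package defaults mirror a far more
# conservative configuration than unit tests need)
fast_fit <- function(..., chains = 2, iter = 1000, target_accept = 0.9,
                     seed = 1) {
  suppressWarnings(zib(..., chains = chains, iter = iter,
                       target_accept = target_accept, seed = seed))
}

fast_aggregate <- function(m, n, ..., chains = 2, iter = 2000,
                           target_accept = 0.9, seed = 1) {
  suppressWarnings(zib_aggregate(m, n, ..., chains = chains, iter = iter,
                                 target_accept = target_accept, seed = seed))
}

# midpoint grid over a prior box used by the brute-force joint-posterior
# oracle
grid_joint <- function(m, n, priors = zib_priors(), k = 400) {
  gw <- priors$omega[1] + diff(priors$omega) / k * (seq_len(k) - 0.5)
  gp <- priors$p[1] + diff(priors$p) / k * (seq_len(k) - 0.5)
  lg <- outer(gw, gp, function(w, p)
    zib_joint_log_posterior(w, p, m, n, priors))
  list(gw = gw, gp = gp, lg = lg,
       hw = diff(priors$omega) / k, hp = diff(priors$p) / k)
}
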