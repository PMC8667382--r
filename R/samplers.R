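# MCMC engines.  Both samplers share the same contract: given a log-posterior
# (with gradient for HMC), an initial point and a per-chain seed they return
# the post-warmup draw matrix on the unconstrained scale plus acceptance
# statistics.  Chains are run serially and are reproducible from the seed.

# --- Hamiltonian Monte Carlo with dual-averaging step-size adaptation and
#     diagonal mass-matrix estimation during warmup.  Trajectory lengths are
#     jittered around a fixed integration time and capped at
#     2^min(max_tree_depth, 10) leapfrog steps.
hmc_chain <- function(lpg, init, iter, warmup, target_accept, max_tree_depth,
                      seed, traj_time = 1.2) {
  set.seed(seed)
  d <- length(init)
  q <- init
  cur <- lpg(q)
  if (!is.finite(cur$lp)) stop("non-finite log-posterior at initial point",
                               call. = FALSE)
  inv_mass <- rep(1, d)
  cap <- 2^min(max_tree_depth, 10L)

  leapfrog <- function(q, r, eps, L) {
    g <- lpg(q)
    for (l in seq_len(L)) {
      r <- r + 0.5 * eps * g$grad
      q <- q + eps * r * inv_mass
      g <- lpg(q)
      if (!is.finite(g$lp)) return(list(q = q, r = r, g = g, ok = FALSE))
      r <- r + 0.5 * eps * g$grad
    }
    list(q = q, r = r, g = g, ok = TRUE)
  }
  hamiltonian <- function(lp, r) -lp + 0.5 * sum(r^2 * inv_mass)

  # reasonable starting step size: scale until one leapfrog step has
  # acceptance probability on the right side of 1/2
  find_eps <- function(q, cur) {
    eps <- 0.1
    r <- stats::rnorm(d) / sqrt(inv_mass)
    h0 <- hamiltonian(cur$lp, r)
    step <- leapfrog(q, r, eps, 1L)
    a <- if (step$ok) exp(h0 - hamiltonian(step$g$lp, step$r)) else 0
    dir <- if (a > 0.5) 1 else -1
    for (i in 1:50) {
      eps <- eps * 2^dir
      step <- leapfrog(q, r, eps, 1L)
      a <- if (step$ok) exp(h0 - hamiltonian(step$g$lp, step$r)) else 0
      if ((dir == 1 && a < 0.5) || (dir == -1 && a > 0.5)) break
    }
    eps
  }

  eps <- find_eps(q, cur)
  mu <- log(10 * eps); h_bar <- 0; log_eps_bar <- 0
  gamma <- 0.05; t0 <- 10; kappa <- 0.75; adapt_t <- 0
  mass_window <- max(50L, floor(warmup / 4))
  window_draws <- matrix(NA_real_, mass_window, d)
  wpos <- 0L
  mass_set_at <- floor(warmup * 0.5)
  draws <- matrix(NA_real_, iter - warmup, d)
  accept_sum <- 0; divergences <- 0L

  for (t in seq_len(iter)) {
    r0 <- stats::rnorm(d) / sqrt(inv_mass)
    h0 <- hamiltonian(cur$lp, r0)
    L <- max(1L, round(traj_time / eps * stats::runif(1, 0.6, 1.4)))
    L <- min(L, cap)
    prop <- leapfrog(q, r0, eps, L)
    h1 <- if (prop$ok) hamiltonian(prop$g$lp, prop$r) else Inf
    dh <- h0 - h1
    if (!is.finite(dh) || dh < -1000) divergences <- divergences + 1L
    a <- min(1, exp(min(dh, 0)))
    if (is.finite(dh) && stats::runif(1) < a) {
      q <- prop$q; cur <- prop$g
    }

    if (t <= warmup) {
      adapt_t <- adapt_t + 1
      h_bar <- (1 - 1 / (adapt_t + t0)) * h_bar +
        (target_accept - a) / (adapt_t + t0)
      log_eps <- mu - sqrt(adapt_t) / gamma * h_bar
      w <- adapt_t^(-kappa)
      log_eps_bar <- w * log_eps + (1 - w) * log_eps_bar
      eps <- exp(log_eps)
      wpos <- wpos %% mass_window + 1L
      window_draws[wpos, ] <- q
      if (t == mass_set_at) {
        v <- apply(window_draws[stats::complete.cases(window_draws), ,
                                drop = FALSE], 2, stats::var)
        v[!is.finite(v) | v < 1e-8] <- 1e-8
        inv_mass <- v
        # restart step-size adaptation around the current value
        eps <- max(eps, 1e-6); mu <- log(10 * eps)
        h_bar <- 0; adapt_t <- 0
      }
      if (t == warmup) eps <- exp(log_eps_bar)
    } else {
      draws[t - warmup, ] <- q
      accept_sum <- accept_sum + a
    }
  }
  list(draws = draws, accept_rate = accept_sum / (iter - warmup),
       step_size = eps, divergences = divergences)
}

# --- Adaptive random-walk Metropolis fallback (Haario-style covariance
#     adaptation during warmup, scale tuned toward 0.234 acceptance).
rwm_chain <- function(lpg, init, iter, warmup, seed, ...) {
  set.seed(seed)
  d <- length(init)
  q <- init
  cur <- lpg(q)
  scale <- 2.38 / sqrt(d)
  chol_cov <- diag(d)
  hist_draws <- matrix(NA_real_, warmup, d)
  draws <- matrix(NA_real_, iter - warmup, d)
  accept_sum <- 0; acc_window <- 0; win <- 50L

  for (t in seq_len(iter)) {
    prop <- q + scale * drop(stats::rnorm(d) %*% chol_cov)
    plp <- lpg(prop)
    a <- min(1, exp(plp$lp - cur$lp))
    if (is.finite(plp$lp) && stats::runif(1) < a) {
      q <- prop; cur <- plp; acc_window <- acc_window + 1
    }
    if (t <= warmup) {
      hist_draws[t, ] <- q
      if (t %% win == 0) {
        rate <- acc_window / win; acc_window <- 0
        scale <- scale * exp(0.8 * (rate - 0.234))
        if (t >= max(100, warmup / 5)) {
          cv <- stats::cov(hist_draws[max(1, t - 500):t, , drop = FALSE])
          ch <- tryCatch(chol(cv + 1e-8 * diag(d)), error = function(e) NULL)
          if (!is.null(ch)) chol_cov <- ch
        }
      }
    } else {
      draws[t - warmup, ] <- q
      accept_sum <- accept_sum + a
    }
  }
  list(draws = draws, accept_rate = accept_sum / (iter - warmup),
       step_size = scale, divergences = 0L)
}

# short gradient-guided climb toward the posterior mode used to center the
# per-chain random initial points
posterior_mode <- function(lpg, d) {
  res <- tryCatch(
    stats::optim(rep(0, d),
                 fn = function(q) -lpg(q)$lp,
                 gr = function(q) -lpg(q)$grad,
                 method = "BFGS", control = list(maxit = 200)),
    error = function(e) NULL)
  if (is.null(res) || any(!is.finite(res$par))) rep(0, d) else res$par
}
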