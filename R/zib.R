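#' Fit a Bayesian zero-inflated Bernoulli model
#'
#' Fits the two-part model in which a binary outcome is the product of a
#' latent exposure indicator and an occurrence indicator:
#' `P(Y = 1) = omega * p`, with logit-linear regressions for both parts,
#' \deqn{\mathrm{logit}(\omega_i) = \theta_0 + \theta_1 X_{1i} + \dots,
#'       \qquad
#'       \mathrm{logit}(p_i) = \beta_0 + \beta_1 Z_{1i} + \dots.}
#' The model formula uses a two-part right-hand side separated by `|`:
#' `y ~ x1 + x2 | x3 + x4` puts `x1, x2` in the exposure (structural) part
#' and `x3, x4` in the occurrence part; a single-part formula uses the same
#' covariates in both parts, and `y ~ 1 | 1` is the covariate-free model.
#'
#' Coefficients get normal(0, sigma^2) priors.  By default sigma is itself
#' estimated with a half-normal hyperprior (scale `hyper_scale`); a fixed
#' value can be supplied through `sigma`.  A covariate-free part is not
#' parameterized through coefficients at all: its probability is sampled
#' directly under its uniform prior from `priors`, which is what makes
#' `omega` and `p` separable without covariates.  If both parts are
#' covariate-free and the two uniform supports overlap, the two zero sources
#' are not identifiable and a warning is issued.
#'
#' The default sampler is a Hamiltonian Monte Carlo sampler with
#' dual-averaging step-size adaptation and diagonal mass-matrix estimation
#' during warmup (`sampler = "hmc"`); `sampler = "rwm"` selects an adaptive
#' random-walk Metropolis fallback with the same draw-structure contract.
#' The default configuration (5 chains of 5000 iterations, half warmup,
#' target acceptance 0.999, maximum tree depth 25) mirrors a deliberately
#' conservative setting for stiff posterior geometry near the prior
#' boundaries; far lighter settings are adequate for routine use.
#'
#' @param formula Two-part model formula (see Details).
#' @param data Data frame containing the outcome and covariates.
#' @param priors A [zib_priors()] object: uniform supports used for
#'   covariate-free parts.
#' @param sigma Fixed prior standard deviation for the coefficients, or
#'   `NULL` (default) for the hierarchical half-normal hyperprior.
#' @param hyper_scale Scale of the half-normal hyperprior on sigma
#'   (default 5).
#' @param chains Number of MCMC chains (default 5).
#' @param iter Iterations per chain, warmup included (default 5000).
#' @param warmup_fraction Fraction of `iter` used for adaptation
#'   (default 0.5).
#' @param target_accept Target average acceptance probability for step-size
#'   adaptation (default 0.999).
#' @param max_tree_depth Cap on leapfrog steps per iteration,
#'   `2^max_tree_depth` (default 25; an internal bound of `2^10` steps
#'   applies).
#' @param sampler `"hmc"` (default) or `"rwm"`.
#' @param seed Integer seed; fits are exactly reproducible from it.
#' @return An object of class `"zib"`: a list with the draws array
#'   (`iterations x chains x parameters`, post-warmup only, probabilities
#'   and sigmas on their natural scale), the per-parameter `summary` (see
#'   [summarize_draws()]), convergence `diagnostics`, the model frame
#'   pieces, and the sampler configuration.  A diagnostics failure
#'   (R-hat > 1.01 or ESS < 100) attaches a warning but never an error.
#' @examples
#' \donttest{
#' d <- zib_sim_regression(400, theta = c(-0.5, -2, -3),
#'                         beta = c(0.5, 2, 3), seed = 1)
#' fit <- zib(y ~ x1 + x2 | x3 + x4, data = d,
#'            chains = 2, iter = 600, target_accept = 0.9, seed = 1)
#' fit
#' coef(fit)
#' }
#' @seealso [zib_exact()] for the closed-form no-covariate posterior,
#'   [zib_aggregate()] for fitting from aggregate counts.
#' @export
zib <- function(formula, data, priors = zib_priors(), sigma = NULL,
                hyper_scale = 5, chains = 5, iter = 5000,
                warmup_fraction = 0.5, target_accept = 0.999,
                max_tree_depth = 25, sampler = c("hmc", "rwm"), seed = 1) {
  cl <- match.call()
  sampler <- match.arg(sampler)
  priors <- as_zib_priors(priors)
  if (warmup_fraction <= 0 || warmup_fraction >= 1)
    stop("'warmup_fraction' must lie in (0, 1)", call. = FALSE)
  if (target_accept <= 0 || target_accept >= 1)
    stop("'target_accept' must lie in (0, 1)", call. = FALSE)
  if (!is.null(sigma) && (!is.finite(sigma) || sigma <= 0))
    stop("'sigma' must be a positive scale", call. = FALSE)

  mf <- parse_zib_formula(formula, data)
  fit_zib_internal(mf$y, mf$X, mf$Z, priors, sigma, hyper_scale, chains,
                   iter, warmup_fraction, target_accept, max_tree_depth,
                   sampler, seed, call = cl, formula = formula,
                   xlevels = mf$xlevels)
}

#' Fit the covariate-free ZIB model from aggregate counts
#'
#' Convenience wrapper around the intercept-only sampler for data given as
#' `m` events out of `n` observations (the sufficient statistics of the
#' covariate-free model).
#'
#' @inheritParams zib
#' @param m Number of events.
#' @param n Total number of observations.
#' @return A fitted `"zib"` object with parameters `omega` and `p`.
#' @examples
#' \donttest{
#' fit <- zib_aggregate(m = 430, n = 1564, chains = 2, iter = 1000,
#'                      target_accept = 0.9, seed = 1)
#' summary(fit)
#' }
#' @export
zib_aggregate <- function(m, n, priors = zib_priors(), chains = 5,
                          iter = 5000, warmup_fraction = 0.5,
                          target_accept = 0.999, max_tree_depth = 25,
                          sampler = c("hmc", "rwm"), seed = 1) {
  check_counts0(m, n)   # n = 0 is allowed: the fit then returns the priors
  sampler <- match.arg(sampler)
  y <- rep(c(1, 0), c(m, n - m))
  fit_zib_internal(y, NULL, NULL, as_zib_priors(priors), NULL, 5, chains,
                   iter, warmup_fraction, target_accept, max_tree_depth,
                   sampler, seed, call = match.call(), formula = y ~ 1 | 1,
                   xlevels = NULL)
}

fit_zib_internal <- function(y, X, Z, priors, sigma, hyper_scale, chains,
                             iter, warmup_fraction, target_accept,
                             max_tree_depth, sampler, seed, call, formula,
                             xlevels) {
  y <- as.numeric(y)
  if (any(y != 0 & y != 1)) stop("outcome must be binary 0/1", call. = FALSE)
  warmup <- floor(iter * warmup_fraction)
  if (iter - warmup < 20L) stop("too few post-warmup iterations",
                                call. = FALSE)

  pw <- make_part(if (!is.null(X) && ncol(X) > 0)
    cbind("(Intercept)" = 1, X) else NULL, priors$omega, sigma, hyper_scale)
  pp <- make_part(if (!is.null(Z) && ncol(Z) > 0)
    cbind("(Intercept)" = 1, Z) else NULL, priors$p, sigma, hyper_scale)

  if (pw$type == "prob" && pp$type == "prob" &&
      priors$omega[2] > priors$p[1] && priors$p[2] > priors$omega[1])
    warning(paste("overlapping uniform prior supports in a covariate-free",
                  "model: the structural and sample zero sources are only",
                  "weakly identified"), call. = FALSE)

  layout <- param_layout(pw, pp)
  lpg <- zib_log_posterior_builder(y, pw, pp, layout)

  set.seed(seed)
  center <- posterior_mode(lpg, layout$d)
  engine <- if (sampler == "hmc") hmc_chain else rwm_chain
  chain_res <- vector("list", chains)
  for (ch in seq_len(chains)) {
    set.seed(seed + 1000L * ch)
    init <- center + stats::rnorm(layout$d, 0, 0.2)
    while (!is.finite(lpg(init)$lp)) init <- center +
        stats::rnorm(layout$d, 0, 0.05)
    chain_res[[ch]] <- engine(lpg, init, iter, warmup, target_accept,
                              max_tree_depth, seed = seed + 1000L * ch + 1L)
  }

  kept <- iter - warmup
  draws <- array(NA_real_, c(kept, chains, layout$d),
                 dimnames = list(NULL, NULL, layout$names))
  for (ch in seq_len(chains))
    draws[, ch, ] <- constrain_draws(chain_res[[ch]]$draws, pw, pp, layout)
  # report sigma rather than log sigma
  for (nm in c("log_sigma_theta", "log_sigma_beta")) {
    if (nm %in% layout$names) {
      j <- match(nm, dimnames(draws)[[3]])
      draws[, , j] <- exp(draws[, , j])
      dimnames(draws)[[3]][j] <- sub("^log_", "", nm)
    }
  }

  smry <- summarize_draws(draws)
  bad <- (is.finite(smry$rhat) & smry$rhat > 1.01) |
    (is.finite(smry$ess) & smry$ess < 100)
  if (chains >= 2 && any(bad))
    warning(sprintf("possible non-convergence for: %s",
                    paste(rownames(smry)[bad], collapse = ", ")),
            call. = FALSE)

  structure(list(
    call = call, formula = formula, y = y, X = X, Z = Z, priors = priors,
    sigma = sigma, hyper_scale = hyper_scale, parts = list(w = pw, p = pp),
    config = list(chains = chains, iter = iter, warmup = warmup,
                  target_accept = target_accept,
                  max_tree_depth = max_tree_depth, sampler = sampler,
                  seed = seed),
    draws = draws, summary = smry,
    accept_rate = vapply(chain_res, `[[`, numeric(1), "accept_rate"),
    divergences = sum(vapply(chain_res, `[[`, integer(1), "divergences")),
    xlevels = xlevels), class = "zib")
}

# two-part formula: y ~ struct | occurrence (single-part formula shares the
# covariates between the two parts)
parse_zib_formula <- function(formula, data) {
  if (length(formula) != 3L) stop("formula needs a response", call. = FALSE)
  rhs <- formula[[3]]
  if (is.call(rhs) && identical(rhs[[1]], as.name("|"))) {
    rhs_w <- rhs[[2]]; rhs_p <- rhs[[3]]
  } else {
    rhs_w <- rhs; rhs_p <- rhs
  }
  fw <- stats::as.formula(call("~", rhs_w))
  fp <- stats::as.formula(call("~", rhs_p))
  fall <- stats::as.formula(call("~", call("+", call("+", formula[[2]],
                                                     rhs_w), rhs_p)))
  mfall <- stats::model.frame(fall, data, na.action = stats::na.omit)
  dropped <- nrow(data) - nrow(mfall)
  if (dropped > 0)
    message(sprintf("dropped %d row(s) with missing values", dropped))
  y <- mfall[[1]]
  if (is.factor(y) || is.logical(y)) y <- as.numeric(y) - is.factor(y)
  design <- function(f) {
    mm <- stats::model.matrix(f, mfall)
    mm[, colnames(mm) != "(Intercept)", drop = FALSE]
  }
  xlev <- lapply(Filter(is.factor, mfall[-1]), levels)
  list(y = y, X = design(fw), Z = design(fp),
       xlevels = if (length(xlev)) xlev else NULL)
}
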