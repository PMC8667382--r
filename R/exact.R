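#' Joint log-posterior of the no-covariate ZIB model
#'
#' Under independent uniform priors on `omega` and `p` the unnormalized joint
#' log-posterior equals the aggregate log-likelihood inside the prior box and
#' `-Inf` outside it:
#' \deqn{f(\omega, p) \propto (\omega p)^m (1 - \omega p)^{n-m}
#'       \, U_{[a_\omega, b_\omega]}(\omega) \, U_{[a_p, b_p]}(p).}
#'
#' @param omega,p Parameter values (vectorized, recycled).
#' @param m,n Aggregate counts: `m` events out of `n` observations.
#' @param priors A [zib_priors()] object (or list coercible to one).
#' @return Unnormalized log-density values.
#' @examples
#' zib_joint_log_posterior(0.37, 0.74, m = 430, n = 1564)
#' zib_joint_log_posterior(0.6, 0.7, m = 430, n = 1564)  # -Inf: omega > 0.5
#' @export
zib_joint_log_posterior <- function(omega, p, m, n, priors = zib_priors()) {
  priors <- as_zib_priors(priors)
  check_counts0(m, n)
  k <- max(length(omega), length(p))
  omega <- rep_len(omega, k); p <- rep_len(p, k)
  out <- rep(-Inf, k)
  inside <- omega >= priors$omega[1] & omega <= priors$omega[2] &
    p >= priors$p[1] & p <= priors$p[2]
  if (any(inside)) {
    t <- omega[inside] * p[inside]
    ll <- numeric(sum(inside))
    if (m > 0) ll <- ll + ifelse(t > 0, m * log(t), -Inf)
    if (n > m) ll <- ll + (n - m) * log1p(-t)
    out[inside] <- ll
  }
  out
}

# counts check that additionally admits the empty-data case n = 0
check_counts0 <- function(m, n) {
  if (length(m) != 1L || length(n) != 1L || !is.finite(m) || !is.finite(n) ||
      m != round(m) || n != round(n) || m < 0 || n < 0 || m > n)
    stop("counts must satisfy 0 <= m <= n", call. = FALSE)
  invisible(NULL)
}

#' Exact marginal posterior densities of the ZIB parameters
#'
#' Integrating the joint posterior over the other parameter gives
#' one-dimensional marginals expressible through the beta distribution
#' function `F(x; m + 1, n - m + 1)` (the regularized incomplete beta,
#' [stats::pbeta()]).  With `omega` uniform on \[a, b\] and `p` uniform on
#' \[c, d\]:
#' \deqn{f(\omega) \propto \frac{F(d\,\omega) - F(c\,\omega)}{\omega}
#'       \quad \text{on } [a, b], \qquad
#'       f(p) \propto \frac{F(b\,p) - F(a\,p)}{p} \quad \text{on } [c, d].}
#' At the default supports these reduce to
#' `(F(omega) - F(omega/2)) / omega` and `F(p/2) / p`.  The apparent
#' singularity at 0 is removable; the analytic limit
#' `(d - c) * dbeta(0; m + 1, n - m + 1)` (zero whenever `m >= 1`) is used
#' there instead of the floating-point ratio.
#'
#' @param omega,p Points at which to evaluate the density (vectorized);
#'   values outside the prior support give 0.
#' @inheritParams zib_joint_log_posterior
#' @param normalize If `TRUE` (default) the density is normalized to
#'   integrate to 1 over the prior support.
#' @return Density values.
#' @examples
#' zib_marginal_omega(c(0.2, 0.37, 0.6), m = 430, n = 1564)
#' zib_marginal_p(0.74, m = 430, n = 1564)
#' @export
zib_marginal_omega <- function(omega, m, n, priors = zib_priors(),
                               normalize = TRUE) {
  priors <- as_zib_priors(priors)
  check_counts0(m, n)
  f <- marginal_unnorm_fun(m, n, scale_lo = priors$p[1],
                           scale_hi = priors$p[2])
  dens <- ifelse(omega >= priors$omega[1] & omega <= priors$omega[2],
                 f(omega), 0)
  if (normalize)
    dens <- dens / marginal_norm_const(f, priors$omega)
  dens
}

#' @rdname zib_marginal_omega
#' @export
zib_marginal_p <- function(p, m, n, priors = zib_priors(), normalize = TRUE) {
  priors <- as_zib_priors(priors)
  check_counts0(m, n)
  f <- marginal_unnorm_fun(m, n, scale_lo = priors$omega[1],
                           scale_hi = priors$omega[2])
  dens <- ifelse(p >= priors$p[1] & p <= priors$p[2], f(p), 0)
  if (normalize)
    dens <- dens / marginal_norm_const(f, priors$p)
  dens
}

# unnormalized marginal [F(hi*x) - F(lo*x)] / x with the x -> 0 limit branch
marginal_unnorm_fun <- function(m, n, scale_lo, scale_hi) {
  a <- m + 1; b <- n - m + 1
  limit0 <- (scale_hi - scale_lo) * if (m == 0) b else 0  # dbeta(0; 1, b) = b
  function(x) {
    out <- numeric(length(x))
    pos <- x > 0
    out[pos] <- (stats::pbeta(scale_hi * x[pos], a, b) -
                   stats::pbeta(scale_lo * x[pos], a, b)) / x[pos]
    out[!pos & x == 0] <- limit0
    out
  }
}

marginal_norm_const <- function(f, support) {
  stats::integrate(f, support[1], support[2], rel.tol = 1e-10,
                   abs.tol = 1e-10, subdivisions = 400L)$value
}

#' Exact posterior for the no-covariate ZIB model
#'
#' Computes the exact (quadrature-based) posterior of `(omega, p)` from
#' aggregate counts under uniform priors: normalized marginal densities,
#' arbitrary posterior quantiles by bisection on the quadrature CDF, and a
#' summary with medians and central 95% credible intervals for `omega`, `p`
#' and the identifiable product `omega * p` (the latter from a midpoint-grid
#' representation of the joint posterior).
#'
#' @inheritParams zib_joint_log_posterior
#' @param grid Number of grid points per axis used for the joint-posterior
#'   grid (product summaries).
#' @return An object of class `"zib_exact"` with components `m`, `n`,
#'   `priors`, `summary` (data frame with `median`, `lower`, `upper` rows for
#'   `omega`, `p`, `omega_p`), `log_norm_const` (log of the joint
#'   normalizing constant, i.e. of the integral of the unnormalized joint
#'   posterior over the prior box), and density/quantile evaluators.
#' @examples
#' fit <- zib_exact(m = 430, n = 1564)
#' fit                      # omega 0.37 (0.27, 0.49); p 0.74 (0.55, 0.99)
#' quantile(fit, c(0.025, 0.5, 0.975), param = "p")
#' @export
zib_exact <- function(m, n, priors = zib_priors(), grid = 400L) {
  priors <- as_zib_priors(priors)
  check_counts0(m, n)
  qfun <- function(param) {
    dens <- if (param == "omega") {
      function(x) zib_marginal_omega(x, m, n, priors)
    } else {
      function(x) zib_marginal_p(x, m, n, priors)
    }
    sup <- if (param == "omega") priors$omega else priors$p
    cdf <- function(x) {
      if (x <= sup[1]) return(0)
      if (x >= sup[2]) return(1)
      stats::integrate(dens, sup[1], x, rel.tol = 1e-10, abs.tol = 1e-10,
                       subdivisions = 400L)$value
    }
    list(dens = dens, cdf = cdf, quantile = function(q) {
      if (any(q <= 0 | q >= 1)) stop("quantile levels must lie in (0, 1)",
                                     call. = FALSE)
      vapply(q, function(qq)
        stats::uniroot(function(x) cdf(x) - qq, sup, tol = 1e-10)$root,
        numeric(1))
    })
  }
  mw <- qfun("omega"); mp <- qfun("p")

  # joint normalizing constant: Beta(m+1, n-m+1) * integral of the
  # unnormalized omega-marginal (log domain: the constant underflows for
  # realistic n)
  fw_un <- marginal_unnorm_fun(m, n, priors$p[1], priors$p[2])
  log_nc <- lbeta(m + 1, n - m + 1) +
    log(marginal_norm_const(fw_un, priors$omega))

  # grid posterior of the product omega * p
  gw <- midpoints(priors$omega, grid); gp <- midpoints(priors$p, grid)
  lg <- outer(gw, gp, function(w, p)
    zib_joint_log_posterior(w, p, m, n, priors))
  wgt <- exp(lg - max(lg)); wgt <- wgt / sum(wgt)
  prod_q <- weighted_quantile(as.vector(outer(gw, gp)), as.vector(wgt),
                              c(0.5, 0.025, 0.975))

  smry <- data.frame(
    median = c(mw$quantile(0.5), mp$quantile(0.5), prod_q[1]),
    lower  = c(mw$quantile(0.025), mp$quantile(0.025), prod_q[2]),
    upper  = c(mw$quantile(0.975), mp$quantile(0.975), prod_q[3]),
    row.names = c("omega", "p", "omega_p"))

  structure(list(m = m, n = n, priors = priors, summary = smry,
                 log_norm_const = log_nc,
                 density = list(omega = mw$dens, p = mp$dens),
                 cdf = list(omega = mw$cdf, p = mp$cdf),
                 qf = list(omega = mw$quantile, p = mp$quantile)),
            class = "zib_exact")
}

midpoints <- function(support, k) {
  h <- diff(support) / k
  support[1] + h * (seq_len(k) - 0.5)
}

weighted_quantile <- function(x, w, probs) {
  o <- order(x)
  cw <- cumsum(w[o])
  vapply(probs, function(q) x[o][which(cw >= q)[1]], numeric(1))
}

#' Posterior quantiles of the exact no-covariate fit
#'
#' @param x A `"zib_exact"` object.
#' @param probs Quantile levels in (0, 1).
#' @param param `"omega"` or `"p"`.
#' @param ... Unused.
#' @return Named numeric vector of posterior quantiles.
#' @export
quantile.zib_exact <- function(x, probs = c(0.025, 0.5, 0.975),
                               param = c("omega", "p"), ...) {
  param <- match.arg(param)
  stats::setNames(x$qf[[param]](probs), paste0(format(100 * probs), "%"))
}

#' @export
print.zib_exact <- function(x, digits = 2, ...) {
  cat("Exact ZIB posterior (no covariates)\n")
  cat(sprintf("  data: m = %d events of n = %d observations\n", x$m, x$n))
  print(x$priors)
  s <- x$summary
  lab <- c(omega = "omega (exposure)", p = "p (occurrence)",
           omega_p = "omega * p")
  for (r in rownames(s))
    cat(sprintf("  %-18s %s (95%% CrI: %s, %s)\n", lab[[r]],
                format(round(s[r, "median"], digits), nsmall = digits),
                format(round(s[r, "lower"], digits), nsmall = digits),
                format(round(s[r, "upper"], digits), nsmall = digits)))
  invisible(x)
}

#' @export
summary.zib_exact <- function(object, ...) object$summary

#' Plot prior and posterior marginals of the exact fit
#'
#' Draws the normalized posterior marginal densities of `omega` and `p`
#' over their prior supports, with the flat prior density overlaid for
#' reference.
#'
#' @param x A `"zib_exact"` object.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.zib_exact <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2)); on.exit(graphics::par(op))
  for (param in c("omega", "p")) {
    sup <- x$priors[[param]]
    g <- seq(sup[1], sup[2], length.out = 401)
    d <- x$density[[param]](g)
    graphics::plot(g, d, type = "l", xlab = param, ylab = "density",
                   main = paste("posterior of", param), ...)
    graphics::abline(h = 1 / diff(sup), lty = 2, col = "grey40")
  }
  invisible(x)
}
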