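#' Simulate ZIB regression data
#'
#' Generates a dataset with the two-layer structure of the zero-inflated
#' Bernoulli regression: four independent standard-normal covariates, a
#' latent exposure indicator driven by `x1, x2` through a logit link, and an
#' outcome that can be 1 only for exposed units, driven by `x3, x4`:
#' \deqn{E_i \sim \mathrm{Bern}(\mathrm{invlogit}(\theta_0 + \theta_1 x_{1i}
#'       + \theta_2 x_{2i})), \quad
#'       Y_i = E_i \cdot \mathrm{Bern}(\mathrm{invlogit}(\beta_0 +
#'       \beta_1 x_{3i} + \beta_2 x_{4i})).}
#' The covariates of the two parts are disjoint by default; with
#' `shared_covariates = TRUE` the occurrence part reuses `x1, x2` instead of
#' fresh `x3, x4` (a stress-test option, not the default design).
#'
#' Random draws are taken in a fixed order (covariates, then exposure, then
#' occurrence), so extending the generator can never reshuffle earlier
#' draws for a given seed.
#'
#' @param n Sample size.
#' @param theta Length-3 coefficient vector `(theta0, theta1, theta2)` of
#'   the exposure (structural) part.
#' @param beta Length-3 coefficient vector `(beta0, beta1, beta2)` of the
#'   occurrence part.
#' @param seed Integer seed; every dataset is reproducible from it.
#' @param shared_covariates Reuse the structural covariates in the
#'   occurrence part (default `FALSE`).
#' @return A `data.frame` with columns `y`, `x1`..`x4` (only `x1`, `x2`
#'   when `shared_covariates = TRUE`), with the latent exposure indicator in
#'   `attr(, "exposure")` and the generating scenario in `attr(, "scenario")`.
#' @examples
#' d <- zib_sim_regression(500, theta = c(-0.5, -2, -3),
#'                         beta = c(0.5, 2, 3), seed = 1)
#' mean(d$y)
#' table(attr(d, "exposure"), d$y)  # y = 1 only where exposed
#' @export
zib_sim_regression <- function(n, theta, beta, seed,
                               shared_covariates = FALSE) {
  stopifnot(n >= 1, length(theta) == 3L, length(beta) == 3L)
  if (any(!is.finite(c(theta, beta)))) stop("coefficients must be finite",
                                            call. = FALSE)
  set.seed(as.integer(seed))
  x1 <- stats::rnorm(n); x2 <- stats::rnorm(n)
  if (shared_covariates) {
    x3 <- x1; x4 <- x2
  } else {
    x3 <- stats::rnorm(n); x4 <- stats::rnorm(n)
  }
  exposure <- stats::rbinom(n, 1, invlogit(theta[1] + theta[2] * x1 +
                                             theta[3] * x2))
  event <- stats::rbinom(n, 1, invlogit(beta[1] + beta[2] * x3 +
                                          beta[3] * x4))
  y <- exposure * event
  d <- if (shared_covariates) data.frame(y = y, x1 = x1, x2 = x2)
  else data.frame(y = y, x1 = x1, x2 = x2, x3 = x3, x4 = x4)
  attr(d, "exposure") <- exposure
  attr(d, "scenario") <- list(theta = theta, beta = beta, n = n, seed = seed,
                              shared_covariates = shared_covariates)
  d
}

#' Simulate covariate-free ZIB data
#'
#' Samples the two latent Bernoulli layers directly: exposure with
#' probability `omega`, then the event with probability `p` among the
#' exposed.  The observed outcome is marginally Bernoulli(`omega * p`).
#'
#' @param n Sample size.
#' @param omega Exposure probability in \[0, 1\].
#' @param p Occurrence probability in \[0, 1\].
#' @param seed Integer seed.
#' @return A `data.frame` with column `y` and the latent exposure indicator
#'   in `attr(, "exposure")`.
#' @examples
#' d <- zib_sim_nocov(1564, omega = 0.39, p = 0.70, seed = 7)
#' sum(d$y)   # close to 0.39 * 0.70 * 1564 ~ 427
#' @export
zib_sim_nocov <- function(n, omega, p, seed) {
  stopifnot(n >= 1)
  check_prob(omega, "omega"); check_prob(p, "p")
  set.seed(as.integer(seed))
  exposure <- stats::rbinom(n, 1, omega)
  y <- exposure * stats::rbinom(n, 1, p)
  d <- data.frame(y = y)
  attr(d, "exposure") <- exposure
  attr(d, "scenario") <- list(omega = omega, p = p, n = n, seed = seed)
  d
}
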