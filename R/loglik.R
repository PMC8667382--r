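#' Aggregate ZIB log-likelihood
#'
#' Without covariates the observed outcomes are marginally Bernoulli with
#' success probability `omega * p`, so the counts `(m, n)` — `m` events out
#' of `n` observations — are sufficient and the log-likelihood is
#' \deqn{\ell(\omega, p) = m \log(\omega p) + (n - m) \log(1 - \omega p).}
#' The likelihood depends on `(omega, p)` only through the product, which is
#' exactly the frequentist non-identifiability the Bayesian priors resolve.
#'
#' Degenerate products incompatible with the data (`omega * p = 0` with
#' `m > 0`, or `= 1` with `m < n`) return `-Inf` rather than raising, so
#' optimizers and samplers can reject such points.
#'
#' @param omega,p ZIB parameters (scalars in \[0, 1\]).
#' @param m Number of events (nonnegative integer).
#' @param n Total number of observations (positive integer, `m <= n`).
#' @return The log-likelihood value (possibly `-Inf`).
#' @examples
#' zib_loglik_aggregate(0.4, 0.8, m = 430, n = 1564)
#' # depends only on the product omega * p:
#' zib_loglik_aggregate(0.8, 0.4, m = 430, n = 1564)
#' @export
zib_loglik_aggregate <- function(omega, p, m, n) {
  check_counts(m, n)
  check_prob(omega, "omega"); check_prob(p, "p")
  t <- omega * p
  ll <- 0
  if (m > 0)  ll <- ll + if (t > 0) m * log(t) else -Inf
  if (n > m)  ll <- ll + (n - m) * log1p(-t)   # log1p(-1) = -Inf, as required
  ll
}

check_counts <- function(m, n) {
  if (length(m) != 1L || length(n) != 1L || !is.finite(m) || !is.finite(n) ||
      m != round(m) || n != round(n) || m < 0 || n < 1 || m > n)
    stop("counts must satisfy 0 <= m <= n with n >= 1", call. = FALSE)
  invisible(NULL)
}

#' Regression ZIB log-likelihood
#'
#' Evaluates the ZIB log-likelihood under the dual logit links
#' `logit(omega_i) = theta' (1, x_i)` and `logit(p_i) = beta' (1, z_i)`.
#' An intercept column is prepended internally, so `X` and `Z` hold
#' covariates only; either may have zero columns (intercept-only part).
#'
#' The `y = 0` term `log(1 - omega_i p_i)` is computed from the
#' complementary probabilities `(1 - omega_i)` and `(1 - p_i)` obtained in
#' the log domain, so it stays accurate when both linear predictors are
#' large and `omega_i p_i` approaches 1.
#'
#' @param theta Coefficient vector of the exposure (structural) part,
#'   length `ncol(X) + 1` (intercept first).
#' @param beta Coefficient vector of the occurrence part, length
#'   `ncol(Z) + 1`.
#' @param y Binary outcome vector (0/1).
#' @param X Numeric matrix of structural-part covariates (`length(y)` rows),
#'   or `NULL` for intercept-only.
#' @param Z Numeric matrix of occurrence-part covariates, or `NULL`.
#' @return The log-likelihood (sum over observations).
#' @examples
#' y <- c(1, 0, 0, 1)
#' zib_loglik_regression(logit(0.4), logit(0.8), y)  # intercept-only
#' @export
zib_loglik_regression <- function(theta, beta, y, X = NULL, Z = NULL) {
  d <- as_outcome_data(y, X, Z)
  if (length(theta) != ncol(d$X) || length(beta) != ncol(d$Z))
    stop("coefficient length does not match design-matrix width", call. = FALSE)
  eta_w <- drop(d$X %*% theta)
  eta_p <- drop(d$Z %*% beta)
  sum(zib_logprob_obs(eta_w, eta_p, d$y))
}

# per-observation log P(y_i | eta_w, eta_p), numerically stable
zib_logprob_obs <- function(eta_w, eta_p, y) {
  out <- numeric(length(y))
  i1 <- y == 1
  if (any(i1))
    out[i1] <- stats::plogis(eta_w[i1], log.p = TRUE) +
      stats::plogis(eta_p[i1], log.p = TRUE)
  if (any(!i1)) {
    qw <- stats::plogis(-eta_w[!i1])   # 1 - omega
    qp <- stats::plogis(-eta_p[!i1])   # 1 - p
    # 1 - omega*p = qw + qp - qw*qp, all terms O(max(qw, qp))
    out[!i1] <- log(qw + qp - qw * qp)
  }
  out
}

# validates and assembles a BinaryOutcomeData-style list with intercept
# columns prepended
as_outcome_data <- function(y, X = NULL, Z = NULL) {
  y <- as.numeric(y)
  if (any(!is.finite(y)) || any(y != 0 & y != 1))
    stop("outcome must contain only 0 or 1", call. = FALSE)
  n <- length(y)
  part <- function(M, nm) {
    if (is.null(M) || NCOL(M) == 0L || (is.matrix(M) && ncol(M) == 0L))
      return(matrix(1, n, 1, dimnames = list(NULL, "(Intercept)")))
    M <- as.matrix(M)
    if (nrow(M) != n)
      stop(sprintf("'%s' must have one row per outcome", nm), call. = FALSE)
    if (any(!is.finite(M)))
      stop(sprintf("'%s' contains non-finite values", nm), call. = FALSE)
    if (is.null(colnames(M))) colnames(M) <- paste0(tolower(nm), seq_len(ncol(M)))
    cbind("(Intercept)" = 1, M)
  }
  list(y = y, X = part(X, "X"), Z = part(Z, "Z"))
}
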