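# Log-posterior construction for the ZIB regression model.
#
# Each model part (exposure / occurrence) is either
#   * "coef": a logit-linear part with intercept + covariates and
#     normal(0, sigma^2) priors on all coefficients; sigma is fixed or
#     hierarchical (half-normal hyperprior, sampled on the log scale), or
#   * "prob": covariate-free, in which case the probability itself is the
#     parameter with a uniform prior on its support, sampled through a
#     scaled-logit transform with the Jacobian included.
#
# The builder returns a function q -> list(lp, grad) over the unconstrained
# parameter vector; when both parts are covariate-free the likelihood
# collapses to the aggregate binomial form in the sufficient statistics
# (m, n), making each evaluation O(1).

make_part <- function(M, support, sigma, hyper_scale) {
  if (is.null(M)) {
    list(type = "prob", lo = support[1], hi = support[2], npar = 1L)
  } else {
    list(type = "coef", M = M, npar = ncol(M),
         sigma = sigma, hierarchical = is.null(sigma),
         hyper_scale = hyper_scale)
  }
}

# parameter layout: [part_w][part_p][log sigma_w?][log sigma_p?]
param_layout <- function(pw, pp) {
  idx <- list(w = seq_len(pw$npar), p = pw$npar + seq_len(pp$npar))
  pos <- pw$npar + pp$npar
  nms <- c(
    if (pw$type == "prob") "omega" else paste0("theta_", colnames(pw$M)),
    if (pp$type == "prob") "p" else paste0("beta_", colnames(pp$M)))
  if (pw$type == "coef" && pw$hierarchical) {
    pos <- pos + 1L; idx$ls_w <- pos; nms <- c(nms, "log_sigma_theta")
  }
  if (pp$type == "coef" && pp$hierarchical) {
    pos <- pos + 1L; idx$ls_p <- pos; nms <- c(nms, "log_sigma_beta")
  }
  list(idx = idx, names = nms, d = pos)
}

# probability (scalar) and its derivative w.r.t. the unconstrained u
prob_transform <- function(part, u) {
  s <- stats::plogis(u)
  list(value = part$lo + (part$hi - part$lo) * s,
       dvalue = (part$hi - part$lo) * s * (1 - s),
       log_jac = log(part$hi - part$lo) +
         stats::plogis(u, log.p = TRUE) + stats::plogis(-u, log.p = TRUE),
       dlog_jac = 1 - 2 * s)
}

zib_log_posterior_builder <- function(y, pw, pp, layout) {
  m <- sum(y); n <- length(y)
  aggregate <- pw$type == "prob" && pp$type == "prob"
  i1 <- y == 1

  function(q) {
    lp <- 0
    grad <- numeric(layout$d)

    # --- linear predictors / probabilities per part
    eval_part <- function(part, qpart) {
      if (part$type == "prob") prob_transform(part, qpart)
      else list(eta = drop(part$M %*% qpart))
    }
    ew <- eval_part(pw, q[layout$idx$w])
    ep <- eval_part(pp, q[layout$idx$p])

    if (aggregate) {
      w <- ew$value; p <- ep$value; t <- w * p
      ll <- 0
      if (m > 0) ll <- ll + m * log(t)
      if (n > m) ll <- ll + (n - m) * log1p(-t)
      dll_dw <- (if (m > 0) m / w else 0) -
        (if (n > m) (n - m) * p / (1 - t) else 0)
      dll_dp <- (if (m > 0) m / p else 0) -
        (if (n > m) (n - m) * w / (1 - t) else 0)
      lp <- ll
      grad[layout$idx$w] <- dll_dw * ew$dvalue
      grad[layout$idx$p] <- dll_dp * ep$dvalue
    } else {
      wv <- if (pw$type == "prob") rep(ew$value, n) else stats::plogis(ew$eta)
      pv <- if (pp$type == "prob") rep(ep$value, n) else stats::plogis(ep$eta)
      qw <- 1 - wv; qp <- 1 - pv
      denom0 <- qw + qp - qw * qp            # = 1 - w*p, stable
      ll <- sum(log(wv[i1])) + sum(log(pv[i1])) + sum(log(denom0[!i1]))
      lp <- ll
      # chain rule per part: d loglik / d eta_i = (1-w_i) for y_i = 1 and
      # -p_i w_i (1-w_i) / (1 - w_i p_i) for y_i = 0 (and symmetrically in p)
      if (pw$type == "coef") {
        g_eta <- ifelse(i1, qw, -pv * wv * qw / denom0)
        grad[layout$idx$w] <- drop(crossprod(pw$M, g_eta))
      } else {
        g_w <- sum(ifelse(i1, 1 / wv, -pv / denom0))
        grad[layout$idx$w] <- g_w * ew$dvalue
      }
      if (pp$type == "coef") {
        g_eta <- ifelse(i1, qp, -wv * pv * qp / denom0)
        grad[layout$idx$p] <- drop(crossprod(pp$M, g_eta))
      } else {
        g_p <- sum(ifelse(i1, 1 / pv, -wv / denom0))
        grad[layout$idx$p] <- g_p * ep$dvalue
      }
    }

    # --- priors / Jacobians
    add_prob_prior <- function(part, tr, id) {
      lp <<- lp + tr$log_jac
      grad[id] <<- grad[id] + tr$dlog_jac
    }
    add_coef_prior <- function(part, id, ls_id) {
      qpart <- q[id]
      if (part$hierarchical) {
        ls <- q[ls_id]; sig <- exp(ls); k <- part$npar
        lp <<- lp - k * ls - sum(qpart^2) / (2 * sig^2) -
          sig^2 / (2 * part$hyper_scale^2) + ls
        grad[id] <<- grad[id] - qpart / sig^2
        grad[ls_id] <<- grad[ls_id] - k + sum(qpart^2) / sig^2 -
          sig^2 / part$hyper_scale^2 + 1
      } else {
        lp <<- lp - sum(qpart^2) / (2 * part$sigma^2)
        grad[id] <<- grad[id] - qpart / part$sigma^2
      }
    }
    if (pw$type == "prob") add_prob_prior(pw, ew, layout$idx$w)
    else add_coef_prior(pw, layout$idx$w, layout$idx$ls_w)
    if (pp$type == "prob") add_prob_prior(pp, ep, layout$idx$p)
    else add_coef_prior(pp, layout$idx$p, layout$idx$ls_p)

    list(lp = lp, grad = grad)
  }
}

# map an unconstrained draw matrix to reported parameters: probabilities for
# "prob" parts, sigmas on the natural scale for hierarchical parts
constrain_draws <- function(draws, pw, pp, layout) {
  out <- draws
  if (pw$type == "prob") {
    u <- draws[, layout$idx$w]
    out[, layout$idx$w] <- pw$lo + (pw$hi - pw$lo) * stats::plogis(u)
  }
  if (pp$type == "prob") {
    u <- draws[, layout$idx$p]
    out[, layout$idx$p] <- pp$lo + (pp$hi - pp$lo) * stats::plogis(u)
  }
  colnames(out) <- layout$names
  out
}
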