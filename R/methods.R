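#' @export
print.zib <- function(x, digits = 2, ...) {
  cat("Bayesian zero-inflated Bernoulli model\n")
  cat("  call: ", deparse(x$call), "\n", sep = "")
  cat(sprintf("  sampler: %s, %d chain(s) x %d iterations (%d warmup)\n",
              x$config$sampler, x$config$chains, x$config$iter,
              x$config$warmup))
  s <- x$summary
  est <- paste0(format(round(s$median, digits), nsmall = digits), " (",
                format(round(s$lower, digits), nsmall = digits), ", ",
                format(round(s$upper, digits), nsmall = digits), ")")
  tab <- data.frame("Estimate (95% CrI)" = est, row.names = rownames(s),
                    check.names = FALSE)
  print(tab)
  if (x$divergences > 0)
    cat(sprintf("  note: %d divergent transition(s)\n", x$divergences))
  invisible(x)
}

#' Posterior summary of a fitted ZIB model
#'
#' @param object A fitted `"zib"` object.
#' @param ... Unused.
#' @return The per-parameter summary data frame (`median`, `lower`,
#'   `upper`, `rhat`, `ess`); see [summarize_draws()].
#' @export
summary.zib <- function(object, ...) object$summary

#' @export
coef.zib <- function(object, ...) {
  stats::setNames(object$summary$median, rownames(object$summary))
}

#' Posterior predictions from a fitted ZIB model
#'
#' Posterior means of the exposure probability (`type = "omega"`), the
#' occurrence probability (`type = "p"`), or the marginal event probability
#' `omega * p` (`type = "response"`, the default), evaluated per draw and
#' averaged.
#'
#' @param object A fitted `"zib"` object.
#' @param newdata Optional data frame of covariates; the training data is
#'   used when omitted.
#' @param type One of `"response"`, `"omega"`, `"p"`.
#' @param ... Unused.
#' @return Numeric vector with one prediction per row.
#' @export
predict.zib <- function(object, newdata = NULL,
                        type = c("response", "omega", "p"), ...) {
  type <- match.arg(type)
  pm <- part_prob_draws(object, newdata)
  out <- switch(type, response = pm$omega * pm$p, omega = pm$omega,
                p = pm$p)
  unname(rowMeans(out))
}

# per-observation draw matrices (n x ndraws) of omega and p
part_prob_draws <- function(object, newdata = NULL) {
  dm <- flat_draws(object)
  nd <- nrow(dm)
  XZ <- if (is.null(newdata)) list(X = object$X, Z = object$Z)
  else newdata_designs(object, newdata)
  one <- function(part, prefix, M, prob_name) {
    if (part$type == "prob")
      return(matrix(dm[, prob_name], nrow = max(1, NROW(M)), ncol = nd,
                    byrow = TRUE))
    cf <- dm[, paste0(prefix, colnames(part$M)), drop = FALSE]
    stats::plogis(cbind(1, M) %*% t(cf))
  }
  nobs <- if (is.null(newdata)) length(object$y) else
    max(NROW(XZ$X), NROW(XZ$Z), 1L)
  ow <- one(object$parts$w, "theta_",
            if (object$parts$w$type == "prob") matrix(0, nobs, 0) else XZ$X,
            "omega")
  op <- one(object$parts$p, "beta_",
            if (object$parts$p$type == "prob") matrix(0, nobs, 0) else XZ$Z,
            "p")
  list(omega = ow, p = op)
}

flat_draws <- function(object) {
  d <- object$draws
  mat <- apply(d, 3, as.vector)
  colnames(mat) <- dimnames(d)[[3]]
  mat
}

newdata_designs <- function(object, newdata) {
  mk <- function(part) {
    if (part$type == "prob") return(matrix(0, nrow(newdata), 0))
    nm <- colnames(part$M)[-1]
    mm <- model_expand(newdata, object$xlevels)
    if (length(setdiff(nm, colnames(mm))))
      stop("newdata lacks required columns: ",
           paste(setdiff(nm, colnames(mm)), collapse = ", "), call. = FALSE)
    mm[, nm, drop = FALSE]
  }
  list(X = mk(object$parts$w), Z = mk(object$parts$p))
}

model_expand <- function(df, xlevels) {
  if (!is.null(xlevels))
    for (nm in names(xlevels))
      if (nm %in% names(df)) df[[nm]] <- factor(df[[nm]], xlevels[[nm]])
  mm <- stats::model.matrix(~ ., df)
  mm[, colnames(mm) != "(Intercept)", drop = FALSE]
}

#' @export
fitted.zib <- function(object, ...) predict(object, type = "response")

#' @export
residuals.zib <- function(object, ...) object$y - fitted(object)

#' Posterior-predictive simulation from a fitted ZIB model
#'
#' Each simulation picks one retained posterior draw, computes the
#' per-observation exposure and occurrence probabilities, and samples the
#' two Bernoulli layers, so the simulations reflect posterior parameter
#' uncertainty as well as sampling noise.
#'
#' @param object A fitted `"zib"` object.
#' @param nsim Number of simulated outcome vectors.
#' @param seed Optional integer seed.
#' @param ... Unused.
#' @return A data frame of `nsim` simulated 0/1 outcome columns, one row
#'   per observation.
#' @export
simulate.zib <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  pm <- part_prob_draws(object)
  nd <- ncol(pm$omega); nobs <- nrow(pm$omega)
  out <- matrix(0L, nobs, nsim)
  for (s in seq_len(nsim)) {
    j <- sample.int(nd, 1)
    expo <- stats::rbinom(nobs, 1, pm$omega[, j])
    out[, s] <- expo * stats::rbinom(nobs, 1, pm$p[, j])
  }
  as.data.frame(out, col.names = paste0("sim_", seq_len(nsim)))
}

#' Trace plots for a fitted ZIB model
#'
#' @param x A fitted `"zib"` object.
#' @param pars Parameter names to plot (defaults to all).
#' @param ... Passed to [graphics::matplot()].
#' @return `x`, invisibly.
#' @export
plot.zib <- function(x, pars = NULL, ...) {
  pn <- dimnames(x$draws)[[3]]
  if (is.null(pars)) pars <- pn
  pars <- intersect(pars, pn)
  op <- graphics::par(mfrow = c(ceiling(length(pars) / 2),
                                min(2, length(pars))))
  on.exit(graphics::par(op))
  for (p in pars)
    graphics::matplot(x$draws[, , p], type = "l", lty = 1,
                      xlab = "iteration", ylab = p, main = p, ...)
  invisible(x)
}
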