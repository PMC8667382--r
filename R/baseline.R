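#' Logistic-regression comparator
#'
#' Fits the standard (frequentist) logistic regression that a pooled
#' analysis would use, via [stats::glm()] with maximum likelihood (IRLS),
#' and reports Wald 95% confidence intervals.  For the intercept-only model
#' the fitted event probability equals the sample proportion `m/n` exactly,
#' and its Wald interval on the probability scale,
#' `m/n +- 1.96 sqrt((m/n)(1 - m/n)/n)`, is reported alongside.
#'
#' Applied to pooled ZIB data this comparator estimates the product
#' `omega * p`, not either parameter — the non-identifiability that the
#' Bayesian model resolves with priors.  With the latent exposure labels
#' known, fitting only the exposed rows estimates the occurrence part
#' directly.
#'
#' @param formula Model formula for [stats::glm()].
#' @param data Data frame.
#' @param subset Optional logical/integer vector selecting rows (e.g. the
#'   exposed subpopulation).
#' @return An object of class `"zib_logistic"`: coefficient table with
#'   standard errors and Wald 95% bounds, the underlying `glm` fit, a
#'   `separation` flag (fitted probabilities numerically 0/1 or runaway
#'   coefficients), and for intercept-only models `proportion` with
#'   `prop_ci`.
#' @examples
#' d <- data.frame(y = rep(c(1, 0), c(430, 1134)))
#' logistic_baseline(y ~ 1, d)   # proportion 0.27 (0.25, 0.30)
#' @export
logistic_baseline <- function(formula, data, subset = NULL) {
  if (!is.null(subset)) data <- data[subset, , drop = FALSE]
  separation <- FALSE
  fit <- withCallingHandlers(
    stats::glm(formula, family = stats::binomial(), data = data,
               control = stats::glm.control(maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1|did not converge",
                conditionMessage(w)))
        separation <<- TRUE
      invokeRestart("muffleWarning")
    })
  if (fit$rank < length(stats::coef(fit)))
    stop("rank-deficient design", call. = FALSE)
  if (!fit$converged || any(abs(stats::coef(fit)) > 15)) separation <- TRUE
  if (separation)
    warning("possible separation: coefficient estimates unreliable",
            call. = FALSE)
  cf <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  z <- stats::qnorm(0.975)
  tab <- data.frame(estimate = cf, se = se, lower = cf - z * se,
                    upper = cf + z * se)
  out <- list(call = match.call(), glm = fit, coefficients = tab,
              separation = separation)
  if (length(cf) == 1L && names(cf) == "(Intercept)") {
    y <- fit$y
    phat <- mean(y)            # equals invlogit(intercept) exactly
    half <- z * sqrt(phat * (1 - phat) / length(y))
    out$proportion <- phat
    out$prop_ci <- c(lower = phat - half, upper = phat + half)
  }
  class(out) <- "zib_logistic"
  out
}

#' @export
print.zib_logistic <- function(x, digits = 2, ...) {
  cat("Logistic regression comparator\n")
  tab <- x$coefficients
  est <- paste0(format(round(tab$estimate, digits), nsmall = digits), " (",
                format(round(tab$lower, digits), nsmall = digits), ", ",
                format(round(tab$upper, digits), nsmall = digits), ")")
  print(data.frame("Coefficient (95% CI)" = est, row.names = rownames(tab),
                   check.names = FALSE))
  if (!is.null(x$proportion))
    cat(sprintf("Event proportion: %.*f (95%% CI: %.*f, %.*f)\n",
                digits, x$proportion, digits, x$prop_ci[1], digits,
                x$prop_ci[2]))
  if (x$separation) cat("warning: possible separation\n")
  invisible(x)
}

#' @export
coef.zib_logistic <- function(object, ...) object$coefficients$estimate

#' Expand aggregate counts to unit records
#'
#' Turns `(m, n)` aggregate counts — `m` events among `n` observations —
#' into a one-column data frame of 0/1 outcomes, for use with functions that
#' take unit-level data.
#'
#' @param m Number of events.
#' @param n Total observations.
#' @return A data frame with binary column `y` (`m` ones then `n - m`
#'   zeros).
#' @examples
#' colSums(binary_from_counts(430, 1564))
#' @export
binary_from_counts <- function(m, n) {
  check_counts(m, n)
  data.frame(y = rep(c(1, 0), c(m, n - m)))
}
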