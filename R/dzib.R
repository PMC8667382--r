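#' Zero-inflated Bernoulli probability mass function
#'
#' A zero-inflated Bernoulli (ZIB) outcome arises from two latent layers: a
#' unit is exposed (at risk) with probability `omega`, and an exposed unit
#' experiences the event with probability `p`.  Only the product is visible
#' in the outcome:
#' \deqn{P(Y = 1) = \omega p, \qquad
#'       P(Y = 0) = (1 - \omega) + \omega (1 - p),}
#' where `1 - omega` is the structural-zero probability (never at risk) and
#' `omega (1 - p)` the sample-zero probability (at risk, no event).
#'
#' @param y Outcome value(s), each exactly 0 or 1.
#' @param omega Exposure probability in \[0, 1\].
#' @param p Occurrence probability among the exposed, in \[0, 1\].
#' @param log If `TRUE`, return log-probabilities.
#' @return Numeric vector of (log-)probabilities, recycled to the common
#'   length of the arguments.
#' @examples
#' dzib(1, omega = 0.5, p = 0.5)   # 0.25
#' dzib(0, omega = 1, p = 0.7)     # plain Bernoulli: 0.3
#' dzib(0:1, omega = 0.37, p = 0.74)
#' @seealso [zib_loglik_aggregate()], [zib_loglik_regression()]
#' @export
dzib <- function(y, omega, p, log = FALSE) {
  if (any(!is.finite(y)) || any(y != 0 & y != 1))
    stop("'y' must contain only 0 or 1", call. = FALSE)
  check_prob(omega, "omega")
  check_prob(p, "p")
  n <- max(length(y), length(omega), length(p))
  y <- rep_len(y, n); omega <- rep_len(omega, n); p <- rep_len(p, n)
  pr <- ifelse(y == 1, omega * p, 1 - omega * p)
  if (log) base::log(pr) else pr
}

check_prob <- function(x, name) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1))
    stop(sprintf("'%s' must lie in [0, 1]", name), call. = FALSE)
  invisible(x)
}
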