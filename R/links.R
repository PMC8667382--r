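#' Logit and inverse-logit links
#'
#' Both model parts of the zero-inflated Bernoulli regression use the logit
#' link: `logit(omega) = theta' x` for the exposure part and
#' `logit(p) = beta' z` for the occurrence part.  `invlogit()` maps a linear
#' predictor back to a probability; it saturates smoothly for large `|x|`
#' instead of overflowing (it delegates to [stats::plogis()], which works in
#' the log domain).
#'
#' @param x Numeric vector of linear-predictor values.
#' @param q Numeric vector of probabilities in (0, 1).
#' @return `invlogit(x)` returns probabilities in (0, 1); `logit(q)` returns
#'   real log-odds.  Both are vectorized and inverse to each other.
#' @examples
#' invlogit(0)            # 0.5
#' invlogit(logit(0.27))  # 0.27
#' @export
invlogit <- function(x) stats::plogis(x)

#' @rdname invlogit
#' @export
logit <- function(q) stats::qlogis(q)
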