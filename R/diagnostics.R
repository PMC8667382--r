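#' Summarize posterior draws
#'
#' Per-parameter posterior median and central 95% interval (empirical 2.5%
#' and 97.5% percentiles pooled across chains), together with the split-R-hat
#' convergence statistic and an autocorrelation-based effective sample size.
#'
#' @param draws A 3-d array of draws with dimensions
#'   (iterations, chains, parameters) — as stored in a fitted [zib()] object
#'   under `$draws` — or a fitted `"zib"` object itself.
#' @return A data frame with one row per parameter and columns `median`,
#'   `lower`, `upper`, `rhat`, `ess`.  With constant draws `rhat` is `NaN`
#'   (no variance to compare).
#' @examples
#' a <- array(rnorm(4000), dim = c(500, 4, 2),
#'            dimnames = list(NULL, NULL, c("a", "b")))
#' summarize_draws(a)
#' @export
summarize_draws <- function(draws) {
  if (inherits(draws, "zib")) draws <- draws$draws
  if (length(dim(draws)) != 3L)
    stop("'draws' must be an (iterations x chains x parameters) array",
         call. = FALSE)
  if (dim(draws)[1] * dim(draws)[2] < 100L)
    stop("need at least 100 retained draws to summarize", call. = FALSE)
  pnames <- dimnames(draws)[[3]]
  if (is.null(pnames)) pnames <- paste0("par", seq_len(dim(draws)[3]))
  rows <- lapply(seq_len(dim(draws)[3]), function(j) {
    mat <- draws[, , j, drop = TRUE]
    if (is.null(dim(mat))) mat <- matrix(mat, ncol = 1)
    pooled <- as.vector(mat)
    qs <- stats::quantile(pooled, c(0.5, 0.025, 0.975), names = FALSE)
    data.frame(median = qs[1], lower = qs[2], upper = qs[3],
               rhat = split_rhat(mat), ess = ess_draws(mat))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- pnames
  out
}

#' Split-R-hat potential scale reduction
#'
#' Each chain is split in half and the classical potential scale reduction
#' factor is computed over the resulting half-chains, so within-chain drift
#' also inflates the statistic.  Returns `NaN` when the draws have no
#' variance.
#'
#' @param mat Matrix of draws, iterations by chains.
#' @return The split-R-hat value (scalar).
#' @export
split_rhat <- function(mat) {
  halves <- split_chains(mat)
  n <- nrow(halves); m <- ncol(halves)
  if (n < 2L) return(NaN)
  means <- colMeans(halves)
  vars <- apply(halves, 2, stats::var)
  w <- mean(vars)
  b <- n * stats::var(means)
  if (!is.finite(w) || w == 0) return(if (b > 0) Inf else NaN)
  sqrt(((n - 1) / n * w + b / n) / w)
}

split_chains <- function(mat) {
  n <- nrow(mat)
  h <- floor(n / 2)
  cbind(mat[seq_len(h), , drop = FALSE],
        mat[seq.int(n - h + 1, n), , drop = FALSE])
}

#' Multi-chain effective sample size
#'
#' Effective sample size from combined within-chain autocorrelations
#' (initial-positive-sequence truncation), on split chains.
#'
#' @param mat Matrix of draws, iterations by chains.
#' @return Estimated effective sample size (scalar; `NaN` for constant
#'   draws).
#' @export
ess_draws <- function(mat) {
  halves <- split_chains(mat)
  n <- nrow(halves); m <- ncol(halves)
  if (n < 4L) return(NaN)
  vars <- apply(halves, 2, stats::var)
  w <- mean(vars)
  if (!is.finite(w) || w == 0) return(NaN)
  b <- n * stats::var(colMeans(halves))
  var_plus <- (n - 1) / n * w + b / n
  # mean autocovariance across chains at each lag
  acovs <- vapply(seq_len(m), function(j) {
    x <- halves[, j] - mean(halves[, j])
    stats::acf(x, lag.max = n - 1, type = "covariance",
               plot = FALSE, demean = FALSE)$acf[, 1, 1]
  }, numeric(n))
  mean_acov <- rowMeans(acovs)
  rho <- 1 - (w - mean_acov) / var_plus   # rho[1] corresponds to lag 0
  # Geyer initial positive sequence on paired lags (1,2), (3,4), ...
  tau <- 0
  t <- 2L
  while (t + 1L <= n) {
    pair <- rho[t] + rho[t + 1L]
    if (!is.finite(pair) || pair < 0) break
    tau <- tau + pair
    t <- t + 2L
  }
  max(1, (n * m) / (1 + 2 * tau))
}

#' Convergence check for a fitted ZIB model
#'
#' Flags parameters whose split-R-hat exceeds `rhat_threshold` or whose
#' effective sample size falls below `ess_threshold`.  With a single chain
#' R-hat is unavailable and the check degrades (with a warning) to the ESS
#' criterion alone.
#'
#' @param fit A fitted `"zib"` object or a draws array (see
#'   [summarize_draws()]).
#' @param rhat_threshold Upper bound on acceptable split-R-hat
#'   (default 1.01).
#' @param ess_threshold Lower bound on acceptable effective sample size
#'   (default 400).
#' @return A data frame with per-parameter `rhat`, `ess`, `pass`, plus an
#'   overall flag in `attr(, "ok")`.
#' @export
check_convergence <- function(fit, rhat_threshold = 1.01,
                              ess_threshold = 400) {
  draws <- if (inherits(fit, "zib")) fit$draws else fit
  single <- dim(draws)[2] < 2L
  if (single)
    warning("single chain: R-hat unavailable, checking ESS only",
            call. = FALSE)
  s <- summarize_draws(draws)
  rhat_ok <- if (single) rep(TRUE, nrow(s)) else
    is.finite(s$rhat) & s$rhat <= rhat_threshold
  ess_ok <- is.finite(s$ess) & s$ess >= ess_threshold
  out <- data.frame(rhat = s$rhat, ess = s$ess, pass = rhat_ok & ess_ok,
                    row.names = rownames(s))
  attr(out, "ok") <- all(out$pass)
  out
}
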