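#' Uniform prior supports for the no-covariate ZIB model
#'
#' In the covariate-free model the likelihood identifies only the product
#' `omega * p`; separation of the two parameters comes entirely from
#' non-overlapping uniform prior supports.  The defaults encode the working
#' assumption that structural zeros are the majority zero source
#' (`omega` uniform on \[0, 0.5\]) while the event is more likely than not
#' among the exposed (`p` uniform on \[0.5, 1\]).
#'
#' @param omega Length-2 numeric, support of the uniform prior on the
#'   exposure probability.
#' @param p Length-2 numeric, support of the uniform prior on the
#'   occurrence probability.
#' @return An object of class `"zib_priors"`.
#' @examples
#' zib_priors()                       # the defaults
#' zib_priors(omega = c(0, 0.3), p = c(0.6, 1))
#' @export
zib_priors <- function(omega = c(0, 0.5), p = c(0.5, 1)) {
  chk <- function(b, nm) {
    if (length(b) != 2L || any(!is.finite(b)) || b[1] < 0 || b[2] > 1 ||
        b[1] >= b[2])
      stop(sprintf("'%s' prior support must be 0 <= lo < hi <= 1", nm),
           call. = FALSE)
    as.numeric(b)
  }
  structure(list(omega = chk(omega, "omega"), p = chk(p, "p")),
            class = "zib_priors")
}

#' @export
print.zib_priors <- function(x, ...) {
  cat(sprintf("ZIB uniform priors: omega ~ U[%g, %g], p ~ U[%g, %g]\n",
              x$omega[1], x$omega[2], x$p[1], x$p[2]))
  invisible(x)
}

as_zib_priors <- function(priors) {
  if (inherits(priors, "zib_priors")) return(priors)
  if (is.list(priors)) return(do.call(zib_priors, priors))
  stop("'priors' must be a zib_priors object or a list(omega=, p=)",
       call. = FALSE)
}
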