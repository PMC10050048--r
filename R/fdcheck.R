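# Richardson-extrapolated finite-difference oracle.
#
# Central differences at two step sizes, combined by Richardson
# extrapolation, with the difference between the refined and coarse
# estimates reported as an error bar.  This harness anchors every
# derivative validation in the test suite; it is deliberately independent
# of the analytic derivative machinery.

#' Finite-difference derivative with Richardson extrapolation
#'
#' @param f Scalar function of a scalar argument.
#' @param x Evaluation point.
#' @param h Coarse step size.
#' @param order 1 (first derivative) or 2 (second derivative).
#' @return List with `value` (extrapolated estimate), `error` (estimated
#'   error bar), `coarse`, `fine` (the two central-difference estimates).
#' @export
fd_oracle <- function(f, x, h = 1e-4, order = 1) {
  est <- function(hh) {
    if (order == 1) (f(x + hh) - f(x - hh)) / (2 * hh)
    else (f(x + hh) - 2 * f(x) + f(x - hh)) / hh^2
  }
  coarse <- est(h)
  fine <- est(h / 2)
  value <- (4 * fine - coarse) / 3
  if (!all(is.finite(c(coarse, fine))))
    stop("non-finite function value in finite-difference oracle")
  list(value = value, error = abs(value - fine), coarse = coarse, fine = fine)
}

#' Mixed second partial derivative by central differences
#'
#' @param f Scalar function of two scalar arguments.
#' @param x,y Evaluation point.
#' @param h Step size (used for both variables).
#' @return The four-point central-difference estimate of d2f/dxdy.
#' @export
fd_mixed <- function(f, x, y, h = 1e-4) {
  (f(x + h, y + h) - f(x + h, y - h) - f(x - h, y + h) + f(x - h, y - h)) /
    (4 * h^2)
}

#' Finite-difference partial derivative over a named parameter vector
#'
#' Convenience wrapper for differentiating a function of a full parameter
#' vector with respect to one (or two) named components.
#'
#' @param fvec Function taking a parameter vector and returning a scalar.
#' @param p Named parameter vector.
#' @param n1 Name of the first parameter.
#' @param n2 Optional name of a second parameter (mixed second derivative).
#' @param h Step size.
#' @param order 1 or 2 (ignored when `n2` given).
#' @return For `n2 = NULL`: the [fd_oracle()] result; otherwise the mixed
#'   second derivative.
#' @export
fd_param <- function(fvec, p, n1, n2 = NULL, h = 1e-4, order = 1) {
  if (is.null(n2)) {
    f1 <- function(x) { pp <- p; pp[n1] <- x; fvec(pp) }
    fd_oracle(f1, p[[n1]], h = h, order = order)
  } else if (n1 == n2) {
    f1 <- function(x) { pp <- p; pp[n1] <- x; fvec(pp) }
    fd_oracle(f1, p[[n1]], h = h, order = 2)
  } else {
    f2 <- function(x, y) { pp <- p; pp[n1] <- x; pp[n2] <- y; fvec(pp) }
    list(value = fd_mixed(f2, p[[n1]], p[[n2]], h = h), error = NA_real_)
  }
}
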