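#' Error function and relatives
#'
#' `erf()` is the Gauss error function, `erfinv()` its inverse, and `er()` the
#' primitive of erf, \eqn{Er(t) = t\,\mathrm{erf}(t) + e^{-t^2}/\sqrt{\pi}},
#' an even function used throughout the closed-form profile integrals.
#'
#' @param x numeric vector.
#' @return numeric vector of the same length.
#' @examples
#' erf(0)            # 0
#' erfinv(erf(0.7))  # 0.7
#' er(0)             # 1/sqrt(pi)
#' @export
erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1

#' @rdname erf
#' @export
erfinv <- function(x) stats::qnorm((x + 1) / 2) / sqrt(2)

#' @rdname erf
#' @export
er <- function(x) x * erf(x) + exp(-x^2) / sqrt(pi)

# Gaussian-derivative kernel d/dx erf(x) = (2/sqrt(pi)) exp(-x^2); internal.
erf_deriv <- function(x) (2 / sqrt(pi)) * exp(-x^2)
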