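#' Physical constants (GROMOS-style units)
#'
#' The package works throughout in nm, ps, u, e, kJ/mol and K.
#' `kb_kjmol` is the Boltzmann constant in kJ mol^-1 K^-1 and
#' `coulomb_prefactor` is 1/(4 pi eps0) in kJ mol^-1 nm e^-2.
#'
#' @format Numeric scalars.
#' @name constants
NULL

#' @rdname constants
#' @export
kb_kjmol <- 0.008314462618

#' @rdname constants
#' @export
coulomb_prefactor <- 138.935458

#' Inverse temperature beta = 1/(kB T)
#'
#' @param temperature Temperature in K.
#' @return beta in mol/kJ.
#' @export
beta_of <- function(temperature) {
  stopifnot(is.numeric(temperature), temperature > 0)
  1 / (kb_kjmol * temperature)
}

## log(sum(exp(x))) with max-subtraction; safe for very negative x
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

logmeanexp <- function(x) logsumexp(x) - log(length(x))

`%||%` <- function(a, b) if (is.null(a)) b else a
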