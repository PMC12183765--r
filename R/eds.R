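#' EDS reference-state parameters
#'
#' @param s Smoothness parameter, 0 < s <= 1. s = 1 is the physical reference
#'   state; s < 1 smooths the barriers between end-states.
#' @param offsets Energy offsets E_i^R (kJ/mol), one per end-state; used to
#'   give all end-states comparable weights in the reference state.
#' @param temperature Temperature (K) fixing beta.
#' @return An object of class `eds_parameters`.
#' @export
eds_parameters <- function(s, offsets, temperature = 298.15) {
  if (!is.numeric(s) || length(s) != 1L || s <= 0 || s > 1) {
    stop("s must be a single value in (0, 1]")
  }
  if (any(!is.finite(offsets))) stop("offsets must be finite")
  structure(list(s = s, offsets = as.numeric(offsets),
                 temperature = temperature,
                 beta = beta_of(temperature)),
            class = "eds_parameters")
}

#' EDS reference-state energy
#'
#' V_R = -1/(beta s) ln sum_i exp(-beta s (V_i - E_i^R)), evaluated with
#' max-subtraction so that it neither overflows nor underflows even for
#' beta*s*|V_i - E_i| of order 1e6. The reference state envelopes the
#' end-states: V_R <= min_i (V_i - E_i^R) always, with the bound approached
#' from below as s grows.
#'
#' @param V Per-end-state potential energies (kJ/mol).
#' @param params An [eds_parameters()] with matching offset length.
#' @return V_R in kJ/mol.
#' @export
reference_energy <- function(V, params) {
  check_state_energies(V, params)
  bs <- params$beta * params$s
  -logsumexp(-bs * (V - params$offsets)) / bs
}

#' EDS end-state weights
#'
#' w_i = softmax over -beta s (V_i - E_i^R); the fraction each end-state
#' contributes to the reference-state force. Weights sum to one; values below
#' 1e-300 after normalization are flushed to zero.
#'
#' @inheritParams reference_energy
#' @return Numeric weight vector summing to 1.
#' @export
state_weights <- function(V, params) {
  check_state_energies(V, params)
  x <- -params$beta * params$s * (V - params$offsets)
  w <- exp(x - max(x))
  w <- w / sum(w)
  w[w < 1e-300] <- 0
  w / sum(w)
}

check_state_energies <- function(V, params) {
  if (length(V) != length(params$offsets)) {
    stop(sprintf("got %d state energies for %d offsets", length(V), length(params$offsets)))
  }
  if (any(!is.finite(V))) {
    stop(sprintf("non-finite end-state energy for state %s",
                 paste(which(!is.finite(V)), collapse = ", ")))
  }
  invisible(TRUE)
}

#' Mix per-state forces into the reference-state force
#'
#' f_k = sum_i w_i (-dV_i/dr_k): the convex combination of the end-state
#' force fields with the weights of the same frame.
#'
#' @param per_state_forces List of n x 3 force matrices, one per end-state.
#' @param w Weights from [state_weights()] for the same configuration.
#' @return n x 3 mixed force matrix.
#' @export
reference_forces <- function(per_state_forces, w) {
  if (length(per_state_forces) != length(w)) stop("forces/weights length mismatch")
  out <- per_state_forces[[1]] * w[1]
  if (length(w) > 1) {
    for (i in 2:length(w)) {
      if (!identical(dim(per_state_forces[[i]]), dim(out))) stop("force shape mismatch")
      out <- out + per_state_forces[[i]] * w[i]
    }
  }
  out
}
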