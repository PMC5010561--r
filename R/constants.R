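# Physical constants used throughout.
# Energies are handled in eV, geometry and dipoles in atomic units.

#' Physical constants
#'
#' Conversion factors and constants used by the package: `hartree_ev`
#' (1 hartree in eV) and `k_boltzmann_ev` (Boltzmann constant in eV/K).
#'
#' @return A named list with elements `hartree_ev` and `k_boltzmann_ev`.
#' @examples
#' xs_constants()$hartree_ev
#' @export
xs_constants <- function() {
  list(hartree_ev = 27.211386245988, k_boltzmann_ev = 8.617333262e-5)
}

.hartree_ev <- 27.211386245988
.kb_ev <- 8.617333262e-5

# Stop with a classed error so callers/tests can distinguish failure modes.
xs_abort <- function(msg, class) {
  rlang::abort(msg, class = c(class, "excitonxs_error"))
}
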