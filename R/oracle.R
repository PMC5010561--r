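# Brute-force reference implementations, used in tests only. They share no
# computational code with the production paths (only the data containers),
# so agreement between the two is a genuine cross-check.

#' Full product-space Hamiltonian by naive double loop (reference)
#'
#' Assembles the exact dimer Hamiltonian over the full product basis with
#' every point-dipole Coulomb element evaluated directly, scalar by scalar,
#' and no coupling-neglect rules. Intended as an independent oracle for
#' [assemble_hamiltonian()]; it is deliberately slow and refuses to
#' approximate: exceeding the size cap is a hard error.
#'
#' @param m1,m2 Validated [monomer_states()] objects.
#' @param geometry A [make_dimer_geometry()] object.
#' @param cap Largest allowed product-space size.
#' @return An `aggregate_hamiltonian` over the full product basis.
#' @export
full_product_hamiltonian <- function(m1, m2, geometry, cap = 2500) {
  n1 <- length(m1$energies); n2 <- length(m2$energies)
  if (n1 * n2 > cap)
    xs_abort(sprintf("product space %d exceeds oracle cap %d", n1 * n2, cap),
             "excitonxs_validation_error")
  # lab-frame dipoles, element by element
  R1 <- m1$orientation
  R2 <- geometry$rotation %*% m2$orientation
  d1 <- array(0 + 0i, dim(m1$dipoles))
  d2 <- array(0 + 0i, dim(m2$dipoles))
  for (a in seq_len(n1)) for (b in seq_len(n1))
    d1[a, b, ] <- R1 %*% m1$dipoles[a, b, ]
  for (a in seq_len(n2)) for (b in seq_len(n2))
    d2[a, b, ] <- R2 %*% m2$dipoles[a, b, ]

  X <- geometry$X12
  R <- sqrt(sum(X^2))
  cfg <- expand.grid(index1 = seq_len(n1), index2 = seq_len(n2))
  energy <- m1$energies[cfg$index1] + m2$energies[cfg$index2]
  ord <- order(energy, cfg$index1, cfg$index2)
  cfg <- cfg[ord, ]; energy <- energy[ord]
  N <- nrow(cfg)
  H <- matrix(0 + 0i, N, N)
  for (p in seq_len(N)) {
    for (q in seq_len(N)) {
      dA <- d1[cfg$index1[p], cfg$index1[q], ]
      dB <- d2[cfg$index2[p], cfg$index2[q], ]
      J <- (sum(dA * dB) - 3 * sum(X * dA) * sum(X * dB) / R^2) / R^3
      H[p, q] <- J * 27.211386245988
    }
    H[p, p] <- H[p, p] + energy[p]
  }
  basis <- tibble::tibble(index1 = as.integer(cfg$index1),
                          index2 = as.integer(cfg$index2),
                          energy = energy,
                          n_excited = as.integer(
                            (m1$manifold[cfg$index1] != "ground") +
                            (m2$manifold[cfg$index2] != "ground")))
  basis <- structure(basis, approximation = "TPA", window = NULL,
                     class = c("exciton_basis", class(basis)))
  structure(list(matrix = H, basis = basis, d1lab = d1, d2lab = d2,
                 geometry = geometry, rules = coupling_rules_off()),
            class = "aggregate_hamiltonian")
}

#' Kramers-Heisenberg amplitude by explicit loop (reference)
#'
#' Evaluates the coherent inner sum over intermediate states term by term at
#' a fixed molecular orientation, as an independent check of the vectorized
#' [rixs_amplitudes()] path.
#'
#' @param eig An `exciton_eigen` object.
#' @param i,f Initial and final eigenstate indices.
#' @param e_exc Excitation energy, eV (unshifted scale).
#' @param e1,e2 Polarization unit vectors in the molecular frame.
#' @param gamma_model A [gamma_model()].
#' @param intermediates Indices of intermediate states in the sum.
#' @return A single complex amplitude.
#' @export
direct_rixs_amplitude <- function(eig, i, f, e_exc, e1, e2, gamma_model,
                                  intermediates = seq_along(eig$values)) {
  stopifnot(i >= 1, i <= length(eig$values),
            f >= 1, f <= length(eig$values))
  amp <- 0 + 0i
  for (n in intermediates) {
    gam <- gamma_of_energy(eig$values[n], gamma_model)
    num <- sum(e2 * eig$dipoles[f, n, ]) * sum(e1 * eig$dipoles[n, i, ])
    amp <- amp + num /
      complex(real = eig$values[i] + e_exc - eig$values[n], imaginary = -gam)
  }
  amp
}
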