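#' Point-dipole Coulomb coupling between two transition dipoles
#'
#' Evaluates the dipole-dipole coupling
#' `J = dA.dB / |X|^3 - 3 (X.dA)(X.dB) / |X|^5`
#' for (possibly complex) transition-dipole vectors in atomic units separated
#' by `X` (a.u.). The contraction is bilinear (no conjugation): Hermiticity of
#' the aggregate Hamiltonian is inherited from the Hermiticity of the monomer
#' dipole matrices, not imposed per element.
#'
#' @param dA,dB Complex (or real) 3-vectors, transition dipoles in a.u.
#' @param X Real 3-vector separating the two dipole centers, a.u.
#' @param units `"hartree"` (native) or `"eV"`.
#' @return The (complex in general) coupling energy.
#' @examples
#' dipole_coupling(c(0, 0, 1), c(0, 0, 1), c(0, 0, 10))  # -2e-3, head-to-tail
#' dipole_coupling(c(0, 0, 1), c(0, 0, 1), c(10, 0, 0))  # +1e-3, side-by-side
#' @export
dipole_coupling <- function(dA, dB, X, units = c("hartree", "eV")) {
  units <- match.arg(units)
  R2 <- sum(X * X)
  if (R2 == 0) xs_abort("zero separation between dipoles",
                        "excitonxs_validation_error")
  R <- sqrt(R2)
  J <- sum(dA * dB) / R^3 - 3 * sum(X * dA) * sum(X * dB) / R^5
  if (units == "eV") J <- J * .hartree_ev
  if (all(Im(J) == 0)) J <- Re(J)
  J
}

#' Coupling-neglect rules for the aggregate Hamiltonian
#'
#' Flags controlling which intermonomer coupling classes enter the
#' Hamiltonian. With all defaults on, couplings between two `g-v` transitions
#' and between a `g-v` and a `v-c` transition are set to zero, and no static
#' dipoles (same state on a monomer, including permanent ground-state
#' dipoles) couple to anything. Couplings among `g-c` and `v-c` transitions
#' (including the `g-c` with `v-c` cross terms) are retained;
#' `neglect_gc_vc = TRUE` drops the cross terms for comparison.
#'
#' @param neglect_gv_gv Zero couplings between two `g-v` transitions.
#' @param neglect_gv_vc Zero couplings between a `g-v` and a `v-c` transition.
#' @param neglect_static Zero all couplings involving a static (same-state)
#'   dipole, and keep the Hamiltonian diagonal at the zeroth-order energies.
#' @param neglect_gc_vc Optionally zero `g-c` with `v-c` cross couplings.
#' @return A named logical list of class `coupling_rules`.
#' @export
coupling_rules <- function(neglect_gv_gv = TRUE, neglect_gv_vc = TRUE,
                           neglect_static = TRUE, neglect_gc_vc = FALSE) {
  structure(list(neglect_gv_gv = neglect_gv_gv,
                 neglect_gv_vc = neglect_gv_vc,
                 neglect_static = neglect_static,
                 neglect_gc_vc = neglect_gc_vc),
            class = "coupling_rules")
}

#' All coupling rules disabled (full point-dipole Hamiltonian)
#' @rdname coupling_rules
#' @export
coupling_rules_off <- function() {
  coupling_rules(FALSE, FALSE, FALSE, FALSE)
}

# Rotate every 3-vector of an (n, n, 3) dipole array by R: d' = R d.
rotate_dipoles <- function(d, R) {
  n <- dim(d)[1]
  flat <- matrix(d, ncol = 3L)         # (n^2, 3)
  array(flat %*% t(R), dim = c(n, n, 3L))
}

# Transition class between two states of one monomer: "static" (same state)
# or the sorted manifold pair, e.g. "gv", "gc", "vc", "gg", "vv", "cc".
.manifold_letter <- c(ground = "g", valence = "v", core = "c")

transition_class_matrix <- function(manifold, idx) {
  letters1 <- .manifold_letter[manifold[idx]]
  a <- matrix(letters1, length(idx), length(idx))
  b <- t(a)
  cls <- matrix(paste0(pmin(a, b), pmax(a, b)), length(idx))
  same <- outer(idx, idx, "==")
  cls[same] <- "static"
  cls
}

#' Assemble the aggregate (dimer) Hamiltonian over an exciton basis
#'
#' Builds the Hermitian matrix of the aggregate Hamiltonian in eV: the
#' diagonal carries the zeroth-order configuration energies `E_A1 + E_B2`,
#' and the element between `|A1 B2>` and `|D1 C2>` is the point-dipole
#' coupling of the monomer-1 transition dipole `d1[A1, D1]` with the
#' monomer-2 transition dipole `d2[B2, C2]` (both taken in the lab frame:
#' each monomer's own orientation is applied, and monomer 2 is additionally
#' rotated per the dimer geometry). Couplings are then zeroed according to
#' the [coupling_rules()].
#'
#' @param basis An [build_basis()] result constructed from `m1`, `m2`.
#' @param m1,m2 The monomer state sets the basis refers to.
#' @param geometry A [make_dimer_geometry()] object.
#' @param rules A [coupling_rules()] object.
#' @param max_rank Largest basis size accepted for dense assembly; above it an
#'   error asks for core-state windowing.
#' @return An object of class `aggregate_hamiltonian`: list with `matrix`
#'   (complex Hermitian, eV), `basis`, lab-frame dipole arrays `d1lab`,
#'   `d2lab`, `geometry` and `rules`.
#' @examples
#' m <- make_toy_monomer(toy_monomer_spec(preset = "minimal-3-state", seed = 1))
#' b <- build_basis(m, m, "TPA")
#' H <- assemble_hamiltonian(b, m, m, make_dimer_geometry(7, 0))
#' max(abs(H$matrix - Conj(t(H$matrix))))  # 0
#' @export
assemble_hamiltonian <- function(basis, m1, m2, geometry,
                                 rules = coupling_rules(),
                                 max_rank = 2500) {
  stopifnot(inherits(basis, "exciton_basis"))
  n <- nrow(basis)
  if (n > max_rank)
    xs_abort(sprintf(paste0(
      "basis rank %d exceeds max_rank = %d for dense diagonalization; ",
      "apply a core-state energy window (see select_core_window / ",
      "build_basis(window=))"), n, max_rank), "excitonxs_validation_error")
  if (max(basis$index1) > length(m1$energies) ||
      max(basis$index2) > length(m2$energies))
    xs_abort("basis indices exceed monomer state counts (basis/monomer mismatch)",
             "excitonxs_format_error")
  zeroth <- m1$energies[basis$index1] + m2$energies[basis$index2]
  if (max(abs(zeroth - basis$energy)) > 1e-9)
    xs_abort("basis energies disagree with monomer energies (basis/monomer mismatch)",
             "excitonxs_format_error")

  d1lab <- rotate_dipoles(m1$dipoles, m1$orientation)
  d2lab <- rotate_dipoles(m2$dipoles, geometry$rotation %*% m2$orientation)

  i1 <- basis$index1; i2 <- basis$index2
  X <- geometry$X12
  R <- sqrt(sum(X * X))
  xhat <- X / R

  # J[p,q] = [d1.d2 - 3 (xhat.d1)(xhat.d2)] / R^3, with d1 = d1lab[i1_p, i1_q, ]
  dot <- matrix(0 + 0i, n, n); xd1 <- dot; xd2 <- dot
  for (k in 1:3) {
    T1 <- d1lab[, , k][i1, i1]
    T2 <- d2lab[, , k][i2, i2]
    dot <- dot + T1 * T2
    xd1 <- xd1 + xhat[k] * T1
    xd2 <- xd2 + xhat[k] * T2
  }
  J <- (dot - 3 * xd1 * xd2) / R^3 * .hartree_ev

  cls1 <- transition_class_matrix(m1$manifold, i1)
  cls2 <- transition_class_matrix(m2$manifold, i2)
  drop <- matrix(FALSE, n, n)
  if (isTRUE(rules$neglect_static))
    drop <- drop | cls1 == "static" | cls2 == "static"
  if (isTRUE(rules$neglect_gv_gv))
    drop <- drop | (cls1 == "gv" & cls2 == "gv")
  if (isTRUE(rules$neglect_gv_vc))
    drop <- drop | (cls1 == "gv" & cls2 == "cv") | (cls1 == "cv" & cls2 == "gv")
  if (isTRUE(rules$neglect_gc_vc))
    drop <- drop | (cls1 == "cg" & cls2 == "cv") | (cls1 == "cv" & cls2 == "cg")
  J[drop] <- 0 + 0i

  H <- J
  diag(H) <- diag(H) + zeroth
  structure(list(matrix = H, basis = basis, d1lab = d1lab, d2lab = d2lab,
                 geometry = geometry, rules = rules),
            class = "aggregate_hamiltonian")
}

#' @export
print.aggregate_hamiltonian <- function(x, ...) {
  cat(sprintf("<aggregate_hamiltonian> rank %d (%s basis), |X12| = %.3f a.u.\n",
              nrow(x$matrix), attr(x$basis, "approximation"),
              sqrt(sum(x$geometry$X12^2))))
  invisible(x)
}

#' Diagonalize an aggregate Hamiltonian
#'
#' Dense Hermitian eigendecomposition of the aggregate Hamiltonian, returning
#' eigenvalues in ascending order, the unitary eigenvector matrix, and the
#' aggregate transition-dipole matrix between eigenstates. The
#' configuration-level dipole between `|A1 B2>` and `|D1 C2>` is
#' `d1[A1, D1]` when the monomer-2 states coincide, `d2[B2, C2]` when the
#' monomer-1 states coincide, and zero when both monomers change (the
#' one-electron dipole operator cannot excite both monomers at once); it is
#' then rotated into the eigenbasis, `D = U^H mu U` componentwise.
#'
#' @param H An [assemble_hamiltonian()] result (or, equivalently, the output
#'   of [full_product_hamiltonian()]).
#' @param hermiticity_tol Largest tolerated deviation of `H` from its
#'   conjugate transpose, in eV.
#' @return An object of class `exciton_eigen`: list with `values` (eV,
#'   ascending), `vectors` (unitary, columns are eigenstates), `dipoles`
#'   (complex `c(N, N, 3)` array between eigenstates, a.u.), and `basis`.
#' @export
diagonalize <- function(H, hermiticity_tol = 1e-8) {
  M <- H$matrix
  dev <- max(abs(M - Conj(t(M))))
  if (dev > hermiticity_tol)
    xs_abort(sprintf("Hamiltonian is not Hermitian: max deviation %.3e eV",
                     dev), "excitonxs_validation_error")
  es <- eigen((M + Conj(t(M))) / 2, symmetric = TRUE)
  ord <- rev(seq_along(es$values))   # eigen() returns descending
  U <- es$vectors[, ord, drop = FALSE]
  vals <- es$values[ord]

  i1 <- H$basis$index1; i2 <- H$basis$index2
  same1 <- outer(i1, i1, "==")
  same2 <- outer(i2, i2, "==")
  n <- length(i1)
  dip <- array(0 + 0i, c(n, n, 3L))
  Uh <- Conj(t(U))
  for (k in 1:3) {
    mu <- matrix(0 + 0i, n, n)
    T1 <- H$d1lab[, , k][i1, i1]
    T2 <- H$d2lab[, , k][i2, i2]
    mu[same2] <- T1[same2]
    mu[same1] <- mu[same1] + T2[same1]
    dip[, , k] <- Uh %*% mu %*% U
  }
  structure(list(values = vals, vectors = U, dipoles = dip, basis = H$basis),
            class = "exciton_eigen")
}

#' Trivial eigen-system of a single monomer
#'
#' Wraps a monomer as a ready-made `exciton_eigen` object (its states are
#' already eigenstates), so the spectrum functions apply unchanged to
#' monomers. Dipoles are taken in the lab frame (monomer orientation
#' applied).
#'
#' @param m A [monomer_states()] object.
#' @return An `exciton_eigen` object with identity eigenvectors.
#' @export
monomer_eigensystem <- function(m) {
  n <- length(m$energies)
  basis <- tibble::tibble(index1 = seq_len(n), index2 = rep(1L, n),
                          energy = m$energies,
                          n_excited = as.integer(m$manifold != "ground"))
  structure(list(values = m$energies,
                 vectors = diag(n) + 0i,
                 dipoles = rotate_dipoles(m$dipoles, m$orientation),
                 basis = basis),
            class = "exciton_eigen")
}

#' @export
print.exciton_eigen <- function(x, ...) {
  cat(sprintf("<exciton_eigen> %d eigenstates, %.4f .. %.4f eV\n",
              length(x$values), min(x$values), max(x$values)))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an exciton eigen-system
#'
#' One row per eigenstate: ascending energy (eV) and the isotropic oscillator
#' weight `|d|^2` of the transition from the lowest eigenstate.
#'
#' @param x An `exciton_eigen` object.
#' @param ... Unused.
#' @return A tibble with columns `state`, `energy`, `dipole_sq_from_lowest`.
#' @method tidy exciton_eigen
#' @export
tidy.exciton_eigen <- function(x, ...) {
  d2 <- vapply(seq_along(x$values), function(p)
    sum(abs(x$dipoles[1L, p, ])^2), numeric(1))
  tibble::tibble(state = seq_along(x$values), energy = x$values,
                 dipole_sq_from_lowest = d2)
}

#' @rdname tidy.exciton_eigen
#' @method glance exciton_eigen
#' @export
glance.exciton_eigen <- function(x, ...) {
  tibble::tibble(n_states = length(x$values),
                 e_min = min(x$values), e_max = max(x$values),
                 trace = sum(x$values))
}
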