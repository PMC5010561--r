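# Fixtures are built in code; no data files.

# Two-level monomer: ground at 0 and one core state at `e_core`, with a real
# ground-core transition dipole `d` (a.u.).
two_level_monomer <- function(e_core = 710, d = c(1, 0, 0)) {
  dip <- array(0 + 0i, c(2, 2, 3))
  dip[1, 2, ] <- d
  dip[2, 1, ] <- Conj(d)
  monomer_states(c(0, e_core), dipoles = dip,
                 manifold = c("ground", "core"))
}

# Monomer with fixed energies and seeded random complex Hermitian dipoles,
# scaled per manifold block (gc strongest). Used where tests need control
# over the level layout (e.g. valence states well separated from the
# elastic line).
random_monomer <- function(energies, manifold, seed,
                           scale_gc = 0.1, scale_vc = 0.04,
                           scale_other = 0.01) {
  n <- length(energies)
  withr::with_seed(seed, {
    d <- array(complex(real = stats::rnorm(3 * n * n),
                       imaginary = stats::rnorm(3 * n * n)),
               dim = c(n, n, 3)) / sqrt(2)
    lab <- substr(manifold, 1, 1)
    pair <- function(a, b) paste(sort(c(a, b)), collapse = "")
    sc <- outer(lab, lab, Vectorize(function(a, b)
      switch(pair(a, b), "cg" = scale_gc, "cv" = scale_vc, scale_other)))
    for (k in 1:3) d[, , k] <- d[, , k] * sc
    d <- (d + Conj(aperm(d, c(2, 1, 3)))) / 2
    for (k in 1:3) diag(d[, , k]) <- Re(diag(d[, , k]))
    monomer_states(energies, dipoles = d, manifold = manifold)
  })
}

# Dimer eigen-system with every intermonomer coupling forced to zero
# (uncoupled limit), from identical monomers at the given geometry.
uncoupled_dimer_eigen <- function(m, geometry = make_dimer_geometry(7, 0)) {
  b <- build_basis(m, m, "TPA")
  H <- assemble_hamiltonian(b, m, m, geometry)
  H$matrix <- diag(b$energy) + 0i
  diagonalize(H)
}

expect_rel_equal <- function(got, want, tol) {
  scale <- max(abs(want))
  expect_lt(max(abs(got - want)) / scale, tol)
}
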