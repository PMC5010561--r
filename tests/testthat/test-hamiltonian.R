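test_that("point-dipole coupling matches closed forms", {
  # collinear head-to-tail: (1 - 3) / R^3
  expect_equal(dipole_coupling(c(0, 0, 1), c(0, 0, 1), c(0, 0, 10)), -2e-3)
  # side-by-side parallel: 1 / R^3
  expect_equal(dipole_coupling(c(0, 0, 1), c(0, 0, 1), c(10, 0, 0)), 1e-3)
  # orthogonal dipoles, both perpendicular to X
  expect_equal(dipole_coupling(c(1, 0, 0), c(0, 1, 0), c(0, 0, 5)), 0)
  expect_error(dipole_coupling(c(1, 0, 0), c(1, 0, 0), c(0, 0, 0)),
               class = "excitonxs_validation_error")
})

test_that("coupling falls off as the inverse cube of the separation", {
  withr::with_seed(21, {
    for (rep in 1:5) {
      dA <- complex(real = rnorm(3), imaginary = rnorm(3))
      dB <- complex(real = rnorm(3), imaginary = rnorm(3))
      X <- rnorm(3)
      expect_equal(dipole_coupling(dA, dB, 2 * X),
                   dipole_coupling(dA, dB, X) / 8)
    }
  })
})

test_that("zero dipoles give a diagonal Hamiltonian with zeroth-order spectrum", {
  m <- monomer_states(c(0, 3, 710), dipoles = array(0 + 0i, c(3, 3, 3)),
                      manifold = c("ground", "valence", "core"))
  b <- build_basis(m, m, "TPA")
  H <- assemble_hamiltonian(b, m, m, make_dimer_geometry(7, 0))
  expect_equal(H$matrix, diag(b$energy) + 0i)
  e <- diagonalize(H)
  expect_equal(e$values, sort(b$energy))
})

test_that("a resonant two-level dimer shows the Davydov splitting 2|J|", {
  s <- 0.7; E <- 710; R <- 7
  m <- two_level_monomer(E, c(s, 0, 0))  # dipole perpendicular to X12 (z)
  b <- build_basis(m, m, "TPA")
  H <- assemble_hamiltonian(b, m, m, make_dimer_geometry(R, 0))
  e <- diagonalize(H)
  J <- s^2 / R^3 * xs_constants()$hartree_ev   # side-by-side: + |d|^2 / R^3
  # the singly core-excited block {cg, gc} splits to E -/+ J; the {gg, cc}
  # block mixes through the retained double (de)excitation coupling
  expect_equal(e$values[2:3], c(E - J, E + J), tolerance = 1e-12)
  expect_equal(e$values[c(1, 4)], E + c(-1, 1) * sqrt(E^2 + J^2),
               tolerance = 1e-12)
  got_split <- e$values[3] - e$values[2]
  # eigenvalue accuracy is relative to the matrix scale (~E)
  expect_lt(abs(got_split - 2 * abs(J)), 1e-12 * E)
  # symmetric/antisymmetric eigenvectors on the resonant block
  blk <- which(abs(e$values - E) < 2 * J + 1e-9)
  for (p in blk) {
    v <- e$vectors[b$energy == E, p]
    expect_equal(abs(v[1]), abs(v[2]), tolerance = 1e-10)
  }
})

test_that("coupling-neglect rules zero the prescribed classes only", {
  m <- make_toy_monomer(toy_monomer_spec(preset = "minimal-3-state"))
  # give all pairwise dipole blocks nonzero entries
  d <- m$dipoles
  d[1, 2, ] <- d[1, 2, ] + c(0.02, 0.01, 0)  # g-v
  d[2, 1, ] <- Conj(d[1, 2, ])
  d[2, 3, ] <- d[2, 3, ] + c(0.03, 0, 0.01)  # v-c
  d[3, 2, ] <- Conj(d[2, 3, ])
  m <- monomer_states(m$energies, dipoles = d, manifold = m$manifold)
  b <- build_basis(m, m, "TPA")
  geo <- make_dimer_geometry(7, 0)
  H <- assemble_hamiltonian(b, m, m, geo, coupling_rules())
  idx <- function(i1, i2) which(b$index1 == i1 & b$index2 == i2)
  # g-v with g-v coupling removed
  expect_identical(H$matrix[idx(2, 1), idx(1, 2)], 0 + 0i)
  # g-v with v-c coupling removed: <v1 g2| H |v1' -> no; use |g1 v2> vs |v1 c2>
  expect_identical(H$matrix[idx(2, 1), idx(2, 3)], 0 + 0i)  # static m1 + v-c m2
  # g-c with g-c retained
  expect_false(H$matrix[idx(3, 1), idx(1, 3)] == 0)
  # independent element-by-element check of every entry
  X <- geo$X12; R <- sqrt(sum(X^2))
  man <- m$manifold
  cls <- function(a, b) {
    if (a == b) return("static")
    paste(sort(substr(c(man[a], man[b]), 1, 1)), collapse = "")
  }
  for (p in seq_len(nrow(b))) for (q in seq_len(nrow(b))) {
    if (p == q) next
    c1 <- cls(b$index1[p], b$index1[q]); c2 <- cls(b$index2[p], b$index2[q])
    dropped <- c1 == "static" || c2 == "static" ||
      (c1 == "gv" && c2 == "gv") ||
      (c1 == "gv" && c2 == "cv") || (c1 == "cv" && c2 == "gv")
    dA <- m$dipoles[b$index1[p], b$index1[q], ]
    dB <- m$dipoles[b$index2[p], b$index2[q], ]
    want <- if (dropped) 0 + 0i else
      (sum(dA * dB) / R^3 - 3 * sum(X * dA) * sum(X * dB) / R^5) *
        xs_constants()$hartree_ev
    expect_equal(H$matrix[p, q], want, tolerance = 1e-14)
  }
})

test_that("assembly stays Hermitian for random complex dipoles and conserves the trace", {
  for (seed in c(31, 32)) {
    m1 <- make_toy_monomer(toy_monomer_spec(n_valence = 3, n_core = 3,
                                            seed = seed))
    m2 <- make_toy_monomer(toy_monomer_spec(n_valence = 2, n_core = 4,
                                            seed = seed + 100))
    b <- build_basis(m1, m2, "TPA")
    H <- assemble_hamiltonian(b, m1, m2, make_dimer_geometry(7, 35))
    expect_equal(max(abs(H$matrix - Conj(t(H$matrix)))), 0)
    e <- diagonalize(H)
    # rule (b) keeps the diagonal at zeroth order, so the trace is conserved
    expect_equal(sum(e$values), sum(b$energy), tolerance = 1e-10)
    # unitarity and reconstruction
    U <- e$vectors
    expect_lt(max(abs(Conj(t(U)) %*% U - diag(nrow(b)))), 1e-10)
    D <- Conj(t(U)) %*% H$matrix %*% U
    expect_lt(max(abs(D - diag(e$values))), 1e-10)
  }
})

test_that("diagonal Hamiltonians keep configuration-level dipoles", {
  m <- monomer_states(c(0, 710),
                      dipoles = {
                        d <- array(0 + 0i, c(2, 2, 3))
                        d[1, 2, 1] <- 0.3 + 0.1i; d[2, 1, 1] <- 0.3 - 0.1i
                        d
                      },
                      manifold = c("ground", "core"))
  # far-apart dimer of a bright and a dark monomer keeps monomer dipoles
  dark <- monomer_states(c(0, 710), dipoles = array(0 + 0i, c(2, 2, 3)),
                         manifold = c("ground", "core"))
  b <- build_basis(m, dark, "TPA")
  H <- assemble_hamiltonian(b, m, dark, make_dimer_geometry(7, 0))
  expect_equal(H$matrix, diag(b$energy) + 0i)  # dark partner: no coupling
  e <- diagonalize(H)
  gg <- which(b$energy == 0)
  cg <- which(b$index1 == 2 & b$index2 == 1)   # bright monomer excited
  expect_equal(e$dipoles[gg, cg, 1], m$dipoles[1, 2, 1])
})

test_that("non-Hermitian matrices are rejected by diagonalize", {
  m <- two_level_monomer()
  b <- build_basis(m, m, "TPA")
  H <- assemble_hamiltonian(b, m, m, make_dimer_geometry(7, 0))
  H$matrix[1, 2] <- H$matrix[1, 2] + 1e-3
  expect_error(diagonalize(H), class = "excitonxs_validation_error")
})

test_that("oversized bases are refused with a pointer to windowing", {
  m <- make_toy_monomer(toy_monomer_spec(n_valence = 4, n_core = 4, seed = 1))
  b <- build_basis(m, m, "TPA")
  expect_error(assemble_hamiltonian(b, m, m, make_dimer_geometry(7, 0),
                                    max_rank = 10),
               "window", class = "excitonxs_validation_error")
})

test_that("tidy and glance summarize eigen-systems", {
  m <- two_level_monomer(710, c(0.5, 0, 0))
  e <- monomer_eigensystem(m)
  td <- tidy(e)
  expect_equal(td$energy, c(0, 710))
  expect_equal(td$dipole_sq_from_lowest, c(0, 0.25))
  gl <- glance(e)
  expect_equal(gl$n_states, 2)
  expect_equal(gl$trace, 710)
})
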