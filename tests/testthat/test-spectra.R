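# Single-band lifetime model used by most toys here.
flat_gamma <- function(g = 0.3) gamma_model(Inf, g)

toy_config <- function(exc, em = NULL, sigma = 0.25, pol = "perpendicular-detection",
                       shift = 0, gm = flat_gamma(), mode = "boltzmann-ground",
                       n_initial = 4, temperature = 300, order = 5) {
  spectroscopy_config(excitation_grid = exc, emission_grid = em,
                      pulse_sigma = sigma, temperature = temperature,
                      polarization = pol, global_shift = shift,
                      gamma_model = gm, initial_state_mode = mode,
                      n_initial = n_initial, quadrature_order = order)
}

test_that("Boltzmann weights follow the closed form and normalize", {
  expect_equal(boltzmann_weights(c(0, 0), 300), c(0.5, 0.5))
  w <- boltzmann_weights(c(0, 0.1), 300)
  kT <- 8.617333262e-5 * 300
  expect_equal(w[2] / w[1], exp(-0.1 / kT), tolerance = 1e-12)
  expect_equal(sum(w), 1)
  expect_equal(boltzmann_weights(c(0, 0.1), 0), c(1, 0))
  expect_error(boltzmann_weights(numeric(), 300),
               class = "excitonxs_format_error")
})

test_that("a single transition yields one oscillator-weighted Voigt line", {
  m <- two_level_monomer(710, c(1, 1, 1))   # |d|^2 = 3
  eig <- monomer_eigensystem(m)
  grid <- seq(705, 715, by = 0.02)
  sp <- xas(eig, toy_config(grid))
  # stick weight w * (E_f - E_i) * |d|^2 / 3 = 710
  want <- 710 * voigt_profile(grid - 710, 0.25, 0.3)
  expect_equal(sp$intensity, want, tolerance = 1e-12)
  # global shift moves the rendered axis
  sh <- xas(eig, toy_config(grid, shift = -2.8))
  expect_equal(grid[which.max(sh$intensity)], 710 - 2.8, tolerance = 0.03)
})

test_that("dark systems give identically zero spectra", {
  dark <- monomer_states(c(0, 710), dipoles = array(0 + 0i, c(2, 2, 3)),
                         manifold = c("ground", "core"))
  sp <- xas(monomer_eigensystem(dark), toy_config(seq(700, 720, 1)))
  expect_true(all(sp$intensity == 0))
})

test_that("XAS of an uncoupled dimer is twice the monomer XAS", {
  m <- random_monomer(c(0, 0, 3.0, 3.7, 710, 711.5),
                      c("ground", "ground", "valence", "valence",
                        "core", "core"), seed = 41)
  grid <- seq(706, 715, by = 0.1)
  cfg <- toy_config(grid)
  mono <- xas(monomer_eigensystem(m), cfg)
  dim_eig <- uncoupled_dimer_eigen(m)
  dimer <- xas(dim_eig, cfg)
  expect_rel_equal(dimer$intensity, 2 * mono$intensity, 1e-10)
})

test_that("a single-intermediate RIXS channel is a Lorentzian resonance", {
  s <- 0.2
  m <- two_level_monomer(710, s * c(0.6, 0, 0.8))
  eig <- monomer_eigensystem(m)
  em <- seq(708, 712, by = 0.05)
  exc <- c(709.4, 710, 710.6)
  gm <- flat_gamma(0.3)
  map <- rixs(eig, toy_config(exc, em, gm = gm), exc,
              orientation = diag(3))
  M <- matrix(map$intensity, length(exc), length(em))
  K <- (s * 0.6) * (s * 0.8)          # (e2.d)(e1.d), e1 = z, e2 = x
  for (ix in seq_along(exc)) {
    iem <- which.min(abs(em - exc[ix]))
    want <- K^2 / ((exc[ix] - 710)^2 + 0.3^2) * dnorm(0, sd = 0.25)
    expect_equal(M[ix, iem], want, tolerance = 1e-10)
  }
  # maximal on resonance
  expect_equal(which.max(sapply(seq_along(exc), function(i)
    max(M[i, ]))), 2L)
})

test_that("two opposite-detuned intermediates interfere destructively", {
  Delta <- 0.4; g <- 0.2; s <- 0.15
  d <- array(0 + 0i, c(3, 3, 3))
  d[1, 2, ] <- s * c(0.6, 0, 0.8); d[2, 1, ] <- Conj(d[1, 2, ])
  d[1, 3, ] <- s * c(0.6, 0, 0.8); d[3, 1, ] <- Conj(d[1, 3, ])
  m <- monomer_states(c(0, 710 - Delta, 710 + Delta), dipoles = d,
                      manifold = c("ground", "core", "core"))
  eig <- monomer_eigensystem(m)
  e1 <- c(0, 0, 1); e2 <- c(1, 0, 0)
  amp <- rixs_amplitudes(eig, 1, 710, e1, e2, flat_gamma(g), finals = 1L)
  K <- (s * 0.6) * (s * 0.8)
  # direct complex arithmetic: 1/(Delta - ig) + 1/(-Delta - ig) = 2ig/(D^2+g^2)
  want <- K * 2i * g / (Delta^2 + g^2)
  expect_equal(amp, want, tolerance = 1e-12)
  expect_equal(Re(amp), 0, tolerance = 1e-15)
})

test_that("inelastic RIXS of an uncoupled dimer is twice the monomer map", {
  m <- random_monomer(c(0, 0, 3.0, 3.7, 710, 711.5),
                      c("ground", "ground", "valence", "valence",
                        "core", "core"), seed = 43)
  exc <- c(710, 711.5)
  # emission grid restricted to the inelastic (valence-loss) region: the
  # coherent elastic line, where both monomers' channels genuinely
  # interfere, sits >= 2 eV away and its Gaussian tail is < 1e-13 here
  em <- seq(705.5, 708, by = 0.1)
  cfg_m <- toy_config(exc, em, mode = "boltzmann-ground")
  # intermediates restricted to the core manifold, as in production use:
  # unwindowed sums also pick up off-resonant permanent-dipole self-terms
  # (n = i, n = f), whose configuration dipole in the dimer is the *sum* of
  # the monomers' static dipoles and which therefore do not add
  win <- c(710.75, 5)
  mono <- rixs(monomer_eigensystem(m), cfg_m, exc, intermediate_window = win)
  dimer <- rixs(uncoupled_dimer_eigen(m), cfg_m, exc,
                intermediate_window = win)
  expect_rel_equal(dimer$intensity, 2 * mono$intensity, 1e-10)
  expect_true(all(dimer$intensity >= 0))
})

test_that("PFY integrates the emission axis (normalization and sub-ranges)", {
  em <- seq(-6, 6, by = 0.01)
  exc <- c(1, 2)
  manual <- structure(
    tibble::tibble(excitation = rep(exc, times = length(em)),
                   emission = rep(em, each = length(exc)),
                   intensity = rep(dnorm(em), each = length(exc))),
    excitation_grid = exc, emission_grid = em,
    class = c("rixs_map", class(tibble::tibble())))
  full <- pfy(manual, -6, 6)
  expect_equal(full$intensity, c(1, 1), tolerance = 1e-6)
  off <- pfy(manual, 3.5, 4)
  expect_lt(max(off$intensity), 1e-3)
  expect_error(pfy(manual, 10, 12), class = "excitonxs_validation_error")
  expect_error(pfy(manual, 2, 1), class = "excitonxs_format_error")
})

test_that("PFY agrees with an independent quadrature of the RIXS map", {
  m <- random_monomer(c(0, 2.5, 710), c("ground", "valence", "core"),
                      seed = 47)
  exc <- c(709.5, 710.2)
  em <- seq(704, 712, by = 0.05)
  map <- rixs(monomer_eigensystem(m), toy_config(exc, em), exc)
  got <- pfy(map, 705, 711.5)
  M <- matrix(map$intensity, length(exc), length(em))
  for (ix in seq_along(exc)) {
    fn <- approxfun(em, M[ix, ])
    # exact integral of the linear interpolant, segment by adaptive segment
    edges <- em[em >= 705 & em <= 711.5]
    want <- sum(vapply(seq_len(length(edges) - 1), function(s)
      stats::integrate(fn, edges[s], edges[s + 1])$value, numeric(1)))
    expect_equal(got$intensity[ix], want, tolerance = 1e-8)
  }
})

test_that("orientational averaging reproduces the 1/3 rule and converges", {
  d <- c(0.2, -0.5, 0.7)
  f <- function(R) as.numeric((c(0, 0, 1) %*% (R %*% d))^2)
  avg <- orientational_average(f, order = 5)
  expect_equal(as.numeric(avg), sum(d^2) / 3, tolerance = 1e-12)
  expect_false(is.null(attr(avg, "order")))
  # an isotropic evaluator averages to itself
  iso <- orientational_average(function(R) 2.5, order = 5)
  expect_equal(as.numeric(iso), 2.5)
})

test_that("averaged spectra are invariant under rigid rotation of the dimer", {
  m <- random_monomer(c(0, 0, 3.0, 710), c("ground", "ground", "valence",
                                           "core"), seed = 53)
  geo <- make_dimer_geometry(7, 90)
  b <- build_basis(m, m, "TPA")
  eig1 <- diagonalize(assemble_hamiltonian(b, m, m, geo))

  # rotate the whole aggregate rigidly by R0
  R0 <- rotation_about_y(37) %*% rotation_about_z(-64)
  m_rot <- m; m_rot$orientation <- R0 %*% m$orientation
  geo_rot <- structure(list(X12 = as.vector(R0 %*% geo$X12),
                            rotation = R0 %*% geo$rotation %*% t(R0),
                            rotation_deg = geo$rotation_deg),
                       class = "dimer_geometry")
  # monomer 2 lab dipoles: geo_rot$rotation %*% R0 = R0 %*% geo$rotation
  m2_rot <- m; m2_rot$orientation <- R0 %*% m$orientation
  eig2 <- diagonalize(assemble_hamiltonian(b, m_rot, m2_rot, geo_rot))

  exc <- c(709.8, 710.4)
  em <- seq(705, 712, by = 0.25)
  cfg <- toy_config(exc, em)
  expect_rel_equal(xas(eig2, cfg)$intensity, xas(eig1, cfg)$intensity, 1e-8)
  expect_rel_equal(rixs(eig2, cfg, exc)$intensity,
                   rixs(eig1, cfg, exc)$intensity, 1e-8)
})

test_that("RIXS peak height scales as the inverse square of the lifetime width", {
  m <- two_level_monomer(710, c(0.2, 0, 0.2))
  eig <- monomer_eigensystem(m)
  em <- seq(709.5, 710.5, by = 0.05)
  h <- function(g) {
    map <- rixs(eig, toy_config(710, em, gm = flat_gamma(g)), 710,
                orientation = diag(3))
    max(map$intensity)
  }
  g0 <- 5   # far-detuned regime: Gamma dominates the denominator
  expect_equal(h(g0) / h(2 * g0), 4, tolerance = 1e-6)
})

test_that("final-state dipole ratio kappa maps to a kappa^2 intensity ratio", {
  kappa <- 0.35
  d <- array(0 + 0i, c(3, 3, 3))
  dir <- c(0.6, 0, 0.8)
  d[1, 3, ] <- 0.2 * dir; d[3, 1, ] <- Conj(d[1, 3, ])           # g-c
  d[2, 3, ] <- kappa * 0.2 * dir; d[3, 2, ] <- Conj(d[2, 3, ])   # v-c
  m <- monomer_states(c(0, 3, 710), dipoles = d,
                      manifold = c("ground", "valence", "core"))
  eig <- monomer_eigensystem(m)
  em <- seq(704, 712, by = 0.05)
  map <- rixs(eig, toy_config(710, em), 710, orientation = diag(3))
  M <- matrix(map$intensity, 1, length(em))
  elastic <- M[1, which.min(abs(em - 710))]
  inelastic <- M[1, which.min(abs(em - 707))]
  expect_equal(inelastic / elastic, kappa^2, tolerance = 1e-10)
})

test_that("an empty intermediate window yields a zero map with a warning", {
  m <- two_level_monomer(710, c(0.3, 0, 0.3))
  eig <- monomer_eigensystem(m)
  em <- seq(709, 711, by = 0.1)
  expect_warning(
    map <- rixs(eig, toy_config(710, em), 710,
                intermediate_window = c(900, 1.25)),
    "window is empty")
  expect_true(all(map$intensity == 0))
  expect_true(attr(map, "window_empty"))
  # a window holding the intermediate reproduces the unwindowed map
  map2 <- rixs(eig, toy_config(710, em), 710,
               intermediate_window = c(710, 1.25), orientation = diag(3))
  map3 <- rixs(eig, toy_config(710, em), 710, orientation = diag(3))
  expect_equal(map2$intensity, map3$intensity)
})

test_that("isotropic RIXS factorizes for a single channel", {
  # single g->c->g channel: isotropic average = |d|^4/9 * Lorentzian * Gauss
  s <- 0.25
  m <- two_level_monomer(710, s * c(0, 0, 1))
  eig <- monomer_eigensystem(m)
  em <- seq(709.8, 710.4, by = 0.05)
  map <- rixs(eig, toy_config(710.3, em, pol = "isotropic"), 710.3)
  iem <- which.min(abs(em - 710.3))
  want <- (s^2 / 3)^2 / ((710.3 - 710)^2 + 0.3^2) * dnorm(0, sd = 0.25)
  M <- matrix(map$intensity, 1, length(em))
  expect_equal(M[1, iem], want, tolerance = 1e-8)
})
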