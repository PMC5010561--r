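#' Spectroscopy configuration
#'
#' Collects the parameters shared by the XAS/RIXS/PFY calculations. Defaults
#' reproduce the study conditions for iron L-edge spectra of a hemin-like
#' complex: a 0.25 eV Gaussian excitation pulse, 300 K, the four-band Fe
#' L-edge lifetime model, perpendicular polarization detection, and a global
#' -2.8 eV shift applied to all rendered energy axes.
#'
#' @param excitation_grid,emission_grid Strictly increasing energy grids (eV,
#'   on the rendered/shifted scale) on which spectra are evaluated.
#' @param pulse_sigma Gaussian standard deviation of the excitation pulse
#'   (eV), `> 0`. Also sets the emission-axis resolution of RIXS maps.
#' @param temperature Temperature in K (`>= 0`) for Boltzmann initial-state
#'   weights.
#' @param polarization `"perpendicular-detection"` (outgoing polarization
#'   analyzed orthogonal to the incoming one, averaged numerically over
#'   molecular orientations) or `"isotropic"` (unanalyzed emission; the
#'   outgoing polarization is summed over a lab triad, which factorizes
#'   analytically).
#' @param global_shift Energy shift (eV) added to all rendered spectra axes;
#'   internally everything is computed on the unshifted monomer energy scale.
#' @param gamma_model A [gamma_model()] providing intermediate-state
#'   Lorentzian widths.
#' @param initial_state_mode `"boltzmann-ground"`: all eigenstates within
#'   `ground_span` of the minimum, Boltzmann-weighted at `temperature`;
#'   `"lowest-kramers"`: the `n_initial` lowest eigenstates with equal
#'   weights (the very-low-temperature choice for dimers, where only the
#'   products of the lowest Kramers doublets are populated).
#' @param ground_span Energy span (eV) above the minimum that counts as the
#'   thermally populated ground manifold in `"boltzmann-ground"` mode.
#' @param n_initial Number of lowest states in `"lowest-kramers"` mode
#'   (4 for a dimer of Kramers doublets, 2 for a monomer).
#' @param quadrature_order Euler-angle quadrature order for numerical
#'   orientational averaging; the product rule is exact for dipole-squared
#'   observables from order 5 on.
#' @return A list of class `spectroscopy_config`.
#' @export
spectroscopy_config <- function(excitation_grid, emission_grid = NULL,
                                pulse_sigma = 0.25, temperature = 300,
                                polarization = c("perpendicular-detection",
                                                 "isotropic"),
                                global_shift = -2.8,
                                gamma_model = fe_ledge_gamma_model(),
                                initial_state_mode = c("boltzmann-ground",
                                                       "lowest-kramers"),
                                ground_span = 0.01, n_initial = 4,
                                quadrature_order = 6) {
  polarization <- match.arg(polarization)
  initial_state_mode <- match.arg(initial_state_mode)
  if (pulse_sigma <= 0)
    xs_abort("`pulse_sigma` must be > 0", "excitonxs_format_error")
  if (temperature < 0)
    xs_abort("`temperature` must be >= 0", "excitonxs_format_error")
  if (is.unsorted(excitation_grid, strictly = TRUE))
    xs_abort("`excitation_grid` must be strictly increasing",
             "excitonxs_format_error")
  if (!is.null(emission_grid) && is.unsorted(emission_grid, strictly = TRUE))
    xs_abort("`emission_grid` must be strictly increasing",
             "excitonxs_format_error")
  structure(list(excitation_grid = excitation_grid,
                 emission_grid = emission_grid,
                 pulse_sigma = pulse_sigma, temperature = temperature,
                 polarization = polarization, global_shift = global_shift,
                 gamma_model = gamma_model,
                 initial_state_mode = initial_state_mode,
                 ground_span = ground_span, n_initial = n_initial,
                 quadrature_order = quadrature_order),
            class = "spectroscopy_config")
}

#' Boltzmann weights of initial states
#'
#' `w_i` proportional to `exp(-(E_i - E_min) / (k_B T))`, normalized to sum
#' to one. At `T = 0` all weight is split equally over the states degenerate
#' with the minimum.
#'
#' @param energies Initial-state energies, eV.
#' @param temperature Temperature in K, `>= 0`.
#' @param degeneracy_tol Energy tolerance (eV) for the `T = 0` degenerate set.
#' @return Numeric weights summing to 1.
#' @examples
#' boltzmann_weights(c(0, 0.1), 300)
#' boltzmann_weights(c(0, 0.1), 0)
#' @export
boltzmann_weights <- function(energies, temperature,
                              degeneracy_tol = 1e-9) {
  if (length(energies) == 0L)
    xs_abort("`energies` is empty", "excitonxs_format_error")
  if (temperature < 0)
    xs_abort("`temperature` must be >= 0", "excitonxs_format_error")
  dE <- energies - min(energies)
  if (temperature == 0) {
    w <- as.numeric(dE <= degeneracy_tol)
  } else {
    w <- exp(-dE / (.kb_ev * temperature))
  }
  w / sum(w)
}

# Initial-state selection shared by xas() and rixs().
select_initial_states <- function(eig, config) {
  E <- eig$values
  if (config$initial_state_mode == "boltzmann-ground") {
    idx <- which(E - min(E) <= config$ground_span)
    w <- boltzmann_weights(E[idx], config$temperature)
  } else {
    n <- min(config$n_initial, length(E))
    idx <- seq_len(n)
    w <- rep(1 / n, n)
  }
  if (length(idx) == 0L)
    xs_abort("no initial states selected", "excitonxs_validation_error")
  list(idx = idx, weights = w)
}

# ---- XAS ----------------------------------------------------------------

#' X-ray absorption spectrum
#'
#' First-order absorption from the thermally populated initial states: each
#' transition `i -> f` contributes a stick of weight
#' `w_i (E_f - E_i) |d_fi|^2 / 3` (the isotropic orientational average of
#' `|e1 . d|^2`), convolved with a Voigt profile whose Lorentzian width is
#' the lifetime `Gamma(E_f)` of the final state and whose Gaussian width is
#' the excitation-pulse `sigma`. The configured global shift is applied to
#' the rendered energy axis.
#'
#' @param eig An `exciton_eigen` object ([diagonalize()] or
#'   [monomer_eigensystem()]).
#' @param config A [spectroscopy_config()].
#' @return A `spectrum_grid` tibble with columns `energy` (eV, shifted scale)
#'   and `intensity` (arbitrary units).
#' @export
xas <- function(eig, config) {
  init <- select_initial_states(eig, config)
  grid <- config$excitation_grid
  out <- numeric(length(grid))
  for (j in seq_along(init$idx)) {
    i <- init$idx[j]
    wi <- init$weights[j]
    dE <- eig$values - eig$values[i]
    d2 <- vapply(seq_along(eig$values), function(f)
      sum(abs(eig$dipoles[f, i, ])^2), numeric(1))
    sticks <- which(seq_along(dE) != i & d2 > 0)
    for (f in sticks) {
      w <- wi * dE[f] * d2[f] / 3
      if (w == 0) next
      gam <- gamma_of_energy(eig$values[f], config$gamma_model)
      out <- out + w * voigt_profile(
        grid - (dE[f] + config$global_shift), config$pulse_sigma, gam)
    }
  }
  spectrum_grid(grid, out, kind = "xas")
}

# ---- RIXS ---------------------------------------------------------------

# Gauss-Legendre nodes/weights on [-1, 1] via the Golub-Welsch Jacobi matrix.
gauss_legendre <- function(n) {
  if (n == 1L) return(list(nodes = 0, weights = 2))
  k <- seq_len(n - 1L)
  b <- k / sqrt(4 * k^2 - 1)
  J <- diag(0, n)
  J[cbind(k, k + 1L)] <- b
  J[cbind(k + 1L, k)] <- b
  es <- eigen(J, symmetric = TRUE)
  list(nodes = rev(es$values), weights = rev(2 * es$vectors[1, ]^2))
}

# Product quadrature over SO(3) (ZYZ Euler angles): equal-spaced alpha and
# gamma (exact for trigonometric degree < n), Gauss-Legendre in cos(beta).
so3_quadrature <- function(order) {
  gl <- gauss_legendre(order)
  alpha <- 2 * pi * (seq_len(order) - 1L) / order
  beta <- acos(gl$nodes)
  rots <- list(); w <- numeric()
  for (ia in seq_len(order)) for (ib in seq_len(order))
    for (ig in seq_len(order)) {
      rots[[length(rots) + 1L]] <-
        rotation_euler_zyz(alpha[ia], beta[ib], alpha[ig])
      w <- c(w, gl$weights[ib] / 2 / order / order)
    }
  list(rotations = rots, weights = w)
}

#' Average an orientation-dependent intensity over the rotation group
#'
#' Numerically averages `evaluator(R)` over molecular orientations `R`
#' (uniform Haar measure on SO(3)) using a product Euler-angle quadrature:
#' equally spaced alpha/gamma nodes and Gauss-Legendre nodes in cos(beta).
#' For intensities that are quartic in dipole projections (XAS and RIXS at
#' fixed polarization), the rule is exact from order 5 on. The order is
#' doubled until the result changes by less than `tol` (relative); failure
#' to converge at `max_order` is an error.
#'
#' @param evaluator Function of a 3x3 rotation matrix returning a numeric
#'   scalar or vector intensity.
#' @param order Starting quadrature order per Euler angle.
#' @param tol Relative convergence tolerance between successive orders.
#' @param max_order Largest order attempted before erroring.
#' @return The averaged intensity, with attribute `order` (the converged
#'   order).
#' @examples
#' d <- c(1, 0, 0)
#' f <- function(R) (c(0, 0, 1) %*% (R %*% d))^2
#' orientational_average(f)  # 1/3
#' @export
orientational_average <- function(evaluator, order = 6, tol = 1e-6,
                                  max_order = 48) {
  run <- function(ord) {
    q <- so3_quadrature(ord)
    acc <- NULL
    for (k in seq_along(q$weights)) {
      v <- evaluator(q$rotations[[k]]) * q$weights[k]
      acc <- if (is.null(acc)) v else acc + v
    }
    acc
  }
  prev <- run(order)
  repeat {
    order2 <- 2L * order
    if (order2 > max_order)
      xs_abort(sprintf(
        "orientational average did not converge below %.1e at order %d",
        tol, order), "excitonxs_validation_error")
    cur <- run(order2)
    scale <- max(abs(cur), .Machine$double.xmin)
    if (max(abs(cur - prev)) / scale < tol) {
      attr(cur, "order") <- order2
      return(cur)
    }
    prev <- cur
    order <- order2
  }
}

# Core RIXS amplitude evaluation (vectorized production path).
# Returns the complex amplitude for every final state at one excitation
# energy, fixed initial state and polarization vectors (molecular frame).
#
# a_f = sum_n (e2 . d_fn) (e1 . d_ni) / (E_i + E_exc - E_n - i Gamma_n)

#' RIXS scattering amplitudes at fixed polarization
#'
#' Vectorized evaluation of the Kramers-Heisenberg inner sum over
#' intermediate states, for one initial state and all final states. This is
#' the production code path underlying [rixs()]; it is exposed so the
#' coherent amplitude can be inspected and cross-checked directly.
#'
#' @param eig An `exciton_eigen` object.
#' @param i Initial-state index.
#' @param e_exc Excitation energy (eV, unshifted scale).
#' @param e1,e2 Real polarization unit vectors of the incoming and outgoing
#'   light in the molecular frame.
#' @param gamma_model A [gamma_model()] for the intermediate-state widths.
#' @param intermediates Integer indices of the intermediate states entering
#'   the coherent sum (defaults to all states).
#' @param finals Integer indices of the final states to evaluate.
#' @return Complex vector of amplitudes, one per entry of `finals`.
#' @export
rixs_amplitudes <- function(eig, i, e_exc, e1, e2, gamma_model,
                            intermediates = seq_along(eig$values),
                            finals = seq_along(eig$values)) {
  En <- eig$values[intermediates]
  gam <- gamma_of_energy(En, gamma_model)
  denom <- complex(real = eig$values[i] + e_exc - En, imaginary = -gam)
  a1 <- (e1[1] * eig$dipoles[intermediates, i, 1] +
         e1[2] * eig$dipoles[intermediates, i, 2] +
         e1[3] * eig$dipoles[intermediates, i, 3])
  M2 <- e2[1] * eig$dipoles[finals, intermediates, 1, drop = FALSE][, , 1] +
        e2[2] * eig$dipoles[finals, intermediates, 2, drop = FALSE][, , 1] +
        e2[3] * eig$dipoles[finals, intermediates, 3, drop = FALSE][, , 1]
  M2 <- matrix(M2, nrow = length(finals))
  as.vector(M2 %*% (a1 / denom))
}

# Intensity for all finals at one orientation R: rotating the aggregate by R
# with fixed lab polarizations equals projecting on R^T e_lab.
rixs_intensity_fixed <- function(eig, i, e_exc, R, polarization, gamma_model,
                                 intermediates, finals) {
  e1m <- as.vector(t(R) %*% c(0, 0, 1))
  if (polarization == "perpendicular-detection") {
    e2m <- as.vector(t(R) %*% c(1, 0, 0))
    abs(rixs_amplitudes(eig, i, e_exc, e1m, e2m, gamma_model,
                        intermediates, finals))^2
  } else {
    # unanalyzed emission: sum |amp|^2 over a complete lab triad / 3,
    # which is orientation-independent in e2 (exact factorization)
    acc <- 0
    for (k in 1:3) {
      e2m <- as.vector(t(R) %*% diag(3)[, k])
      acc <- acc + abs(rixs_amplitudes(eig, i, e_exc, e1m, e2m, gamma_model,
                                       intermediates, finals))^2
    }
    acc / 3
  }
}

#' Resonant inelastic X-ray scattering map
#'
#' Kramers-Heisenberg RIXS: for each Boltzmann-weighted initial state `i`,
#' final state `f`, and excitation energy, the coherent sum over intermediate
#' states `n` (optionally restricted to an energy window) is evaluated with
#' state-dependent Lorentzian widths `Gamma_n`, squared, and averaged over
#' molecular orientations according to the polarization geometry. The
#' emission-energy delta is replaced by a Gaussian of the pulse width; the
#' configured global shift is applied to both rendered axes.
#'
#' @param eig An `exciton_eigen` object.
#' @param config A [spectroscopy_config()]; must carry an `emission_grid`.
#' @param excitation_energies Excitation energies in eV on the physical
#'   (unshifted) scale; the returned map's excitation axis carries the shift.
#' @param intermediate_window Optional `c(center, half_width)` (eV, unshifted
#'   scale) or a [select_core_window()] result restricting the intermediate
#'   states in the coherent sum. An empty window yields an all-zero map with
#'   a warning and attribute `window_empty`.
#' @param orientation Optional fixed 3x3 rotation matrix: skip orientational
#'   averaging and evaluate at this single molecular orientation (lab
#'   polarizations `e1 = z`, and `e2 = x` for perpendicular detection).
#' @return A `rixs_map` tibble with columns `excitation`, `emission`,
#'   `intensity`, and grid attributes.
#' @export
rixs <- function(eig, config, excitation_energies,
                 intermediate_window = NULL, orientation = NULL) {
  if (is.null(config$emission_grid))
    xs_abort("config lacks an `emission_grid`", "excitonxs_format_error")
  init <- select_initial_states(eig, config)
  N <- length(eig$values)
  finals <- seq_len(N)
  intermediates <- seq_len(N)
  window_empty <- FALSE
  if (!is.null(intermediate_window)) {
    if (is.list(intermediate_window))
      intermediate_window <- c(intermediate_window$center,
                               intermediate_window$half_width)
    intermediates <- which(
      abs(eig$values - intermediate_window[1]) <= intermediate_window[2])
    if (length(intermediates) == 0L) {
      warning("intermediate-state window is empty: RIXS map is zero")
      window_empty <- TRUE
    }
  }

  n_exc <- length(excitation_energies)
  em <- config$emission_grid
  map <- matrix(0, n_exc, length(em))

  # The product Euler-angle rule is exact for intensities quartic in the
  # dipole projections from order 5 on, so a single fixed-order pass
  # suffices here (orientational_average() provides the generic
  # convergence-controlled variant).
  quad <- if (is.null(orientation) && !window_empty)
    so3_quadrature(max(config$quadrature_order, 5L))

  if (!window_empty) {
    # I[exc, f] per initial state, then spread along the emission axis
    for (j in seq_along(init$idx)) {
      i <- init$idx[j]
      wi <- init$weights[j]
      I_exc_f <- matrix(0, n_exc, N)
      for (ix in seq_len(n_exc)) {
        evalf <- function(R) rixs_intensity_fixed(
          eig, i, excitation_energies[ix], R, config$polarization,
          config$gamma_model, intermediates, finals)
        I_exc_f[ix, ] <- if (is.null(orientation)) {
          acc <- 0
          for (k in seq_along(quad$weights))
            acc <- acc + quad$weights[k] * evalf(quad$rotations[[k]])
          acc
        } else {
          evalf(orientation)
        }
      }
      for (f in seq_len(N)) {
        colf <- I_exc_f[, f] * wi
        if (all(colf == 0)) next
        centers <- excitation_energies + eig$values[i] - eig$values[f] +
          config$global_shift
        for (ix in seq_len(n_exc)) {
          if (colf[ix] == 0) next
          map[ix, ] <- map[ix, ] +
            colf[ix] * stats::dnorm(em - centers[ix], sd = config$pulse_sigma)
        }
      }
    }
  }

  exc_out <- excitation_energies + config$global_shift
  out <- tibble::tibble(
    excitation = rep(exc_out, times = length(em)),
    emission = rep(em, each = n_exc),
    intensity = as.vector(map))
  structure(out, excitation_grid = exc_out, emission_grid = em,
            window_empty = window_empty,
            class = c("rixs_map", class(out)))
}

# Recover the dense intensity matrix (excitation x emission) of a rixs_map.
rixs_matrix <- function(map) {
  exc <- attr(map, "excitation_grid")
  em <- attr(map, "emission_grid")
  matrix(map$intensity, length(exc), length(em))
}

# ---- PFY ----------------------------------------------------------------

#' Partial fluorescence yield
#'
#' Integrates a RIXS map over the emission axis between `e_min` and `e_max`
#' (trapezoidal rule on the emission-grid points inside the closed interval),
#' yielding one intensity per excitation energy.
#'
#' @param map A [rixs()] result.
#' @param e_min,e_max Emission-energy integration bounds (eV, on the map's
#'   rendered scale), `e_min < e_max`, overlapping the emission grid.
#' @return A `spectrum_grid` tibble over the map's excitation axis.
#' @export
pfy <- function(map, e_min, e_max) {
  stopifnot(inherits(map, "rixs_map"))
  if (e_min >= e_max)
    xs_abort("need e_min < e_max", "excitonxs_format_error")
  em <- attr(map, "emission_grid")
  sel <- which(em >= e_min & em <= e_max)
  if (length(sel) < 2L)
    xs_abort("emission grid has no overlap with [e_min, e_max]",
             "excitonxs_validation_error")
  M <- rixs_matrix(map)[, sel, drop = FALSE]
  x <- em[sel]
  h <- diff(x)
  w <- c(h / 2, 0) + c(0, h / 2)        # trapezoid weights
  spectrum_grid(attr(map, "excitation_grid"), as.vector(M %*% w),
                kind = "pfy")
}

# ---- SpectrumGrid container ---------------------------------------------

#' One-dimensional spectrum container
#'
#' @param energies Strictly increasing energy grid, eV.
#' @param intensities Non-negative intensities (arbitrary units).
#' @param kind Label such as `"xas"` or `"pfy"`.
#' @return A tibble of class `spectrum_grid`.
#' @export
spectrum_grid <- function(energies, intensities, kind = "spectrum") {
  if (length(energies) != length(intensities))
    xs_abort("energy and intensity grids differ in length",
             "excitonxs_format_error")
  if (any(intensities < -1e-12))
    xs_abort("negative intensities", "excitonxs_validation_error")
  out <- tibble::tibble(energy = energies,
                        intensity = pmax(intensities, 0))
  structure(out, kind = kind, class = c("spectrum_grid", class(out)))
}

#' Write a spectrum or RIXS map as two-column / gridded text
#'
#' `spectrum_grid` objects are written as two columns (energy, intensity);
#' `rixs_map` objects as three columns (excitation, emission, intensity).
#' Units are eV and arbitrary intensity units.
#'
#' @param x A `spectrum_grid` or `rixs_map`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(x, path) {
  utils::write.table(as.data.frame(x), path, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
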