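#' Specification for a synthetic toy monomer
#'
#' Describes the manifold layout of a seeded synthetic monomer: a small
#' ground manifold of Kramers pairs, a valence manifold up to
#' `valence_span`, and a core manifold inside `core_range`, with complex
#' random transition dipoles whose block scales mirror the dominance of the
#' 2p -> 3d (ground-core) transitions over valence-core and ground-valence
#' ones. The hemin-like defaults emulate an iron porphyrin L-edge layout:
#' valence states up to 7.3 eV and core states between 710.6 and 732.9 eV.
#'
#' @param n_ground Number of ground-manifold states (default 2, one Kramers
#'   pair; use 6 for a sextet split into three doublets).
#' @param ground_splitting Energy step (eV) between successive Kramers
#'   doublets of the ground manifold; partners within a doublet are exactly
#'   degenerate.
#' @param n_valence Number of valence-excited states.
#' @param valence_span Upper edge (eV) of the valence manifold.
#' @param n_core Number of core-excited states.
#' @param core_range Two-vector: energy range (eV) of the core manifold.
#' @param dipole_scale_gc,dipole_scale_vc,dipole_scale_gv RMS scales (a.u.)
#'   of the ground-core, valence-core, and ground-valence (plus
#'   intra-manifold/static) dipole blocks.
#' @param seed Integer seed; identical specs and seeds give bit-identical
#'   monomers.
#' @param preset One of `"minimal-3-state"` (one ground, one valence at 2 eV,
#'   one core at 710 eV, deterministic real dipoles),
#'   `"hemin-like-small"` (6 ground + 12 valence + 24 core), or
#'   `"hemin-like-full-counts"` (6 ground + 96 valence + 690 core, matching
#'   the 102 valence-manifold / 690 core bookkeeping). A preset overrides the
#'   count/range arguments.
#' @return A list of class `toy_monomer_spec`.
#' @export
toy_monomer_spec <- function(n_ground = 2, ground_splitting = 0.001,
                             n_valence = 8, valence_span = 7.3,
                             n_core = 12, core_range = c(710.6, 732.9),
                             dipole_scale_gc = 0.1, dipole_scale_vc = 0.03,
                             dipole_scale_gv = 0.01, seed = 1,
                             preset = NULL) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("minimal-3-state", "hemin-like-small",
                                  "hemin-like-full-counts"))
    if (preset == "minimal-3-state") {
      n_ground <- 1; n_valence <- 1; n_core <- 1
    } else if (preset == "hemin-like-small") {
      n_ground <- 6; n_valence <- 12; n_core <- 24
    } else {
      n_ground <- 6; n_valence <- 96; n_core <- 690
    }
  }
  if (n_ground < 1 || n_valence < 0 || n_core < 0)
    xs_abort("state counts must be non-negative (and n_ground >= 1)",
             "excitonxs_format_error")
  if (ground_splitting < 0 || valence_span <= 0 ||
      core_range[1] >= core_range[2])
    xs_abort("energy ranges must be ordered and positive",
             "excitonxs_format_error")
  if (n_core > 0 && valence_span >= core_range[1])
    xs_abort("valence and core manifold ranges overlap",
             "excitonxs_format_error")
  if (any(c(dipole_scale_gc, dipole_scale_vc, dipole_scale_gv) < 0))
    xs_abort("dipole scales must be >= 0", "excitonxs_format_error")
  structure(list(n_ground = n_ground, ground_splitting = ground_splitting,
                 n_valence = n_valence, valence_span = valence_span,
                 n_core = n_core, core_range = core_range,
                 dipole_scale_gc = dipole_scale_gc,
                 dipole_scale_vc = dipole_scale_vc,
                 dipole_scale_gv = dipole_scale_gv,
                 seed = as.integer(seed), preset = preset),
            class = "toy_monomer_spec")
}

#' Generate a seeded synthetic monomer
#'
#' Draws a reproducible [monomer_states()] object from a
#' [toy_monomer_spec()]: ground Kramers doublets at multiples of the ground
#' splitting, valence energies uniform in `[0.1, valence_span]`, core
#' energies uniform in `core_range`, and a random complex dipole matrix with
#' Hermitian symmetry enforced, uniformly distributed phases (spin-orbit
#' coupled states have genuinely complex dipoles), block-wise scales per the
#' spec, and real static (diagonal) dipoles. The `"minimal-3-state"` preset
#' instead yields a deterministic three-level monomer (g, v at 2 eV, c at
#' 710 eV) with simple real dipoles for closed-form tests.
#'
#' @param spec A [toy_monomer_spec()].
#' @return A validated `monomer_states` object.
#' @examples
#' m <- make_toy_monomer(toy_monomer_spec(seed = 42))
#' table(m$manifold)
#' @export
make_toy_monomer <- function(spec) {
  stopifnot(inherits(spec, "toy_monomer_spec"))
  if (identical(spec$preset, "minimal-3-state"))
    return(minimal_three_state_monomer())
  withr::with_seed(spec$seed, {
    e_ground <- rep(seq_len(ceiling(spec$n_ground / 2)) - 1L,
                    each = 2L)[seq_len(spec$n_ground)] * spec$ground_splitting
    e_val <- if (spec$n_valence > 0)
      sort(stats::runif(spec$n_valence, 0.1, spec$valence_span)) else numeric()
    e_core <- if (spec$n_core > 0)
      sort(stats::runif(spec$n_core, spec$core_range[1], spec$core_range[2]))
      else numeric()
    energies <- c(e_ground, e_val, e_core)
    manifold <- c(rep("ground", spec$n_ground),
                  rep("valence", spec$n_valence),
                  rep("core", spec$n_core))
    n <- length(energies)

    scale_of <- function(a, b) {
      pair <- paste(sort(c(a, b)), collapse = "-")
      switch(pair,
             "core-ground" = spec$dipole_scale_gc,
             "core-valence" = spec$dipole_scale_vc,
             spec$dipole_scale_gv)   # gv, intra-manifold, static
    }
    smat <- outer(manifold, manifold, Vectorize(scale_of))
    d <- array(complex(
      real = stats::rnorm(3 * n * n), imaginary = stats::rnorm(3 * n * n)),
      dim = c(n, n, 3L)) / sqrt(2)
    for (k in 1:3) d[, , k] <- d[, , k] * smat
    d <- (d + Conj(aperm(d, c(2L, 1L, 3L)))) / 2       # Hermitian symmetry
    for (k in 1:3) diag(d[, , k]) <- Re(diag(d[, , k])) # static dipoles real
    monomer_states(energies, dipoles = d, manifold = manifold,
                   spin = "mixed")
  })
}

# Deterministic closed-form toy: ground, valence (2 eV), core (710 eV).
minimal_three_state_monomer <- function() {
  d <- array(0 + 0i, c(3, 3, 3))
  d[1, 3, 1] <- 0.10; d[3, 1, 1] <- 0.10   # g-c along x
  d[2, 3, 2] <- 0.05; d[3, 2, 2] <- 0.05   # v-c along y
  d[1, 2, 3] <- 0.01; d[2, 1, 3] <- 0.01   # g-v along z
  monomer_states(c(0, 2, 710), dipoles = d,
                 manifold = c("ground", "valence", "core"))
}
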