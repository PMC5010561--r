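#' Monomer state set
#'
#' Container for the electronic-structure data of one monomer: spin-orbit
#' coupled state energies (eV, relative to the monomer ground state), spin
#' multiplicity labels, manifold tags (`ground`/`valence`/`core`), the complex
#' transition-dipole matrix (atomic units), and the monomer's position and
#' orientation in the lab frame.
#'
#' States are stored sorted by ascending energy; `index_map` records the
#' position each input state was given on construction, so external state
#' labels remain traceable. The dipole array `d[A, B, k]` holds the Cartesian
#' component `k` of the matrix element `<A| d |B>` and must be Hermitian as a
#' vector-valued matrix, `d[A, B, ] == Conj(d[B, A, ])`.
#'
#' @param energies Numeric vector of state energies in eV relative to the
#'   lowest state; the minimum over the ground manifold must be 0.
#' @param manifold Character vector of per-state tags, each one of
#'   `"ground"`, `"valence"`, `"core"`. If `NULL`, tags are assigned with
#'   [classify_manifolds()] using `ground_span` and `core_threshold`.
#' @param dipoles Complex array of dimension `c(n, n, 3)` in atomic units.
#' @param spin Per-state spin multiplicity labels (integers or `"mixed"` for
#'   spin-orbit coupled states). Recycled if length 1.
#' @param center Numeric 3-vector, monomer center in atomic units.
#' @param orientation 3x3 proper rotation matrix giving the monomer frame in
#'   the lab frame; applied to all dipole vectors when the monomer enters an
#'   aggregate.
#' @param ground_span,core_threshold Passed to [classify_manifolds()] when
#'   `manifold` is `NULL`.
#' @param hermiticity_tol Maximum componentwise deviation allowed between
#'   `dipoles` and its conjugate transpose, in atomic units.
#'
#' @return An object of class `monomer_states`.
#' @seealso [load_monomer()], [write_monomer()], [make_toy_monomer()]
#' @examples
#' d <- array(0+0i, c(2, 2, 3))
#' d[1, 2, 3] <- 0.5; d[2, 1, 3] <- 0.5
#' m <- monomer_states(c(0, 710), dipoles = d, manifold = c("ground", "core"))
#' m$manifold
#' @export
monomer_states <- function(energies, dipoles, manifold = NULL, spin = "mixed",
                           center = c(0, 0, 0), orientation = diag(3),
                           ground_span = 0.01, core_threshold = 100,
                           hermiticity_tol = 1e-10) {
  n <- length(energies)
  if (n == 0L) xs_abort("`energies` is empty", "excitonxs_format_error")
  if (is.null(manifold)) {
    manifold <- classify_manifolds(energies, ground_span, core_threshold)
    manifold <- as.character(manifold)
  }
  spin <- as.character(spin)
  if (length(spin) == 1L) spin <- rep(spin, n)
  ord <- order(energies)              # stable for ties
  x <- structure(
    list(
      energies    = as.numeric(energies)[ord],
      spin        = spin[ord],
      manifold    = manifold[ord],
      dipoles     = dipoles[ord, ord, , drop = FALSE],
      center      = as.numeric(center),
      orientation = orientation,
      index_map   = order(ord)        # original position -> sorted position
    ),
    class = "monomer_states"
  )
  validate_monomer(x, hermiticity_tol = hermiticity_tol)
}

#' Validate a monomer state set
#'
#' Checks all `monomer_states` invariants: consistent lengths, legal manifold
#' tags, a non-empty ground manifold whose minimum energy is zero, core
#' energies strictly above all valence energies, Hermiticity of the dipole
#' array, and a proper rotation for `orientation`.
#'
#' @param x A `monomer_states` object.
#' @param hermiticity_tol Maximum componentwise deviation (a.u.) tolerated
#'   between the dipole array and its conjugate transpose.
#' @return `x`, invisibly unchanged, if valid; otherwise an error of class
#'   `excitonxs_format_error` or `excitonxs_validation_error`.
#' @export
validate_monomer <- function(x, hermiticity_tol = 1e-10) {
  n <- length(x$energies)
  if (n == 0L) xs_abort("field `energies`: empty", "excitonxs_format_error")
  if (length(x$manifold) != n)
    xs_abort("field `manifold`: length mismatch with `energies`",
             "excitonxs_format_error")
  if (length(x$spin) != n)
    xs_abort("field `spin_multiplicity`: length mismatch with `energies`",
             "excitonxs_format_error")
  bad <- setdiff(unique(x$manifold), c("ground", "valence", "core"))
  if (length(bad))
    xs_abort(paste0("field `manifold`: unknown tag ", bad[1]),
             "excitonxs_format_error")
  if (!identical(dim(x$dipoles), c(n, n, 3L)))
    xs_abort(sprintf("field `dipoles`: dimension must be (%d, %d, 3)", n, n),
             "excitonxs_format_error")
  if (length(x$center) != 3L)
    xs_abort("field `center`: must be a 3-vector", "excitonxs_format_error")
  if (!identical(dim(x$orientation), c(3L, 3L)))
    xs_abort("field `orientation`: must be a 3x3 matrix",
             "excitonxs_format_error")

  g <- x$energies[x$manifold == "ground"]
  if (length(g) == 0L)
    xs_abort("ground manifold is empty", "excitonxs_validation_error")
  if (abs(min(g)) > 1e-9)
    xs_abort("minimum ground-manifold energy is not 0",
             "excitonxs_validation_error")
  v <- x$energies[x$manifold == "valence"]
  co <- x$energies[x$manifold == "core"]
  if (length(co) && length(v) && min(co) <= max(v))
    xs_abort("core-manifold energies must strictly exceed all valence energies",
             "excitonxs_validation_error")

  dev <- max(abs(x$dipoles - Conj(aperm(x$dipoles, c(2L, 1L, 3L)))))
  if (dev > hermiticity_tol)
    xs_abort(sprintf(
      "dipole matrix is not Hermitian: max deviation %.3e a.u. exceeds %.1e",
      dev, hermiticity_tol), "excitonxs_validation_error")

  rtr <- crossprod(x$orientation)
  if (max(abs(rtr - diag(3))) > 1e-8 || abs(det(x$orientation) - 1) > 1e-8)
    xs_abort("field `orientation`: not a proper rotation matrix",
             "excitonxs_validation_error")
  invisible(x)
}

#' @export
print.monomer_states <- function(x, ...) {
  tab <- table(factor(x$manifold, c("ground", "valence", "core")))
  cat(sprintf("<monomer_states> %d states (%d ground, %d valence, %d core)\n",
              length(x$energies), tab[1], tab[2], tab[3]))
  cat(sprintf("  energy range: %.4f .. %.4f eV\n",
              min(x$energies), max(x$energies)))
  invisible(x)
}

#' Classify states into ground / valence / core manifolds by energy
#'
#' States with `E <= ground_span` are tagged `ground`, states with
#' `ground_span < E < core_threshold` are `valence`, and `E >= core_threshold`
#' are `core`. The default `ground_span` of 0.01 eV captures Kramers partners
#' of an odd-electron ground state whose degeneracy is only weakly lifted by
#' spin-orbit coupling.
#'
#' @param energies Energies in eV relative to the ground state (a state with
#'   `E == 0` must be present).
#' @param ground_span Upper edge (eV, inclusive) of the ground manifold.
#' @param core_threshold Lower edge (eV, inclusive) of the core manifold.
#' @return Character vector of tags with attribute `no_core` set to `TRUE`
#'   (and a warning emitted) when no state reaches `core_threshold`.
#' @examples
#' classify_manifolds(c(0, 1.5, 711), ground_span = 0.01, core_threshold = 100)
#' @export
classify_manifolds <- function(energies, ground_span = 0.01,
                               core_threshold = 100) {
  if (length(energies) == 0L)
    xs_abort("`energies` is empty", "excitonxs_format_error")
  if (ground_span < 0 || ground_span >= core_threshold)
    xs_abort("need 0 <= ground_span < core_threshold",
             "excitonxs_format_error")
  if (min(abs(energies)) > 1e-9)
    xs_abort("no state at E = 0: energies must be relative to the ground state",
             "excitonxs_validation_error")
  tags <- ifelse(energies <= ground_span, "ground",
                 ifelse(energies < core_threshold, "valence", "core"))
  if (!any(tags == "core")) {
    warning("no state at or above `core_threshold`: core manifold is empty")
    attr(tags, "no_core") <- TRUE
  }
  tags
}

#' Spin-multiplet bookkeeping table
#'
#' Pairs of (spin multiplicity, number of spin-free states), used to count the
#' spin-orbit coupled states a given set of spin-free multiplets expands into.
#'
#' @param multiplicity Integer vector of spin multiplicities (2S + 1 >= 1).
#' @param n_states Integer vector of spin-free state counts (>= 0).
#' @return A tibble of class `multiplet_count`.
#' @examples
#' multiplet_count(c(6, 4), c(16, 174))
#' @export
multiplet_count <- function(multiplicity, n_states) {
  multiplicity <- as.integer(multiplicity)
  n_states <- as.integer(n_states)
  if (length(multiplicity) != length(n_states))
    xs_abort("`multiplicity` and `n_states` must have the same length",
             "excitonxs_format_error")
  if (any(multiplicity < 1L))
    xs_abort("multiplicities must be positive", "excitonxs_validation_error")
  if (any(n_states < 0L))
    xs_abort("state counts must be non-negative", "excitonxs_validation_error")
  out <- tibble::tibble(multiplicity = multiplicity, n_states = n_states)
  class(out) <- c("multiplet_count", class(out))
  out
}

#' Count spin-orbit coupled states
#'
#' Each spin-free multiplet of multiplicity `2S + 1` expands into `2S + 1`
#' spin-orbit coupled components, so the SOC state count is
#' `sum(multiplicity * n_states)`.
#'
#' @param counts A [multiplet_count()] table (or anything coercible: a
#'   two-column data frame `multiplicity`, `n_states`).
#' @return Integer total number of SOC states.
#' @examples
#' count_soc_states(multiplet_count(c(6, 4), c(16, 174)))  # 792
#' @export
count_soc_states <- function(counts) {
  if (!inherits(counts, "multiplet_count"))
    counts <- multiplet_count(counts$multiplicity, counts$n_states)
  sum(as.numeric(counts$multiplicity) * as.numeric(counts$n_states))
}
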