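#' Build a one- or two-particle exciton basis for a dimer
#'
#' Constructs the ordered list of product configurations `|A1 B2>` used to
#' represent aggregate states. With `approximation = "OPA"` (one-particle
#' approximation) the basis holds all ground-manifold products plus
#' configurations in which exactly one monomer is excited (valence or core);
#' with `"TPA"` (two-particle approximation) doubly excited products
#' `|a1 b2>` are added as well, which for a dimer spans the full product space
#' and is exact. An optional energy window drops every configuration that
#' contains a core state lying outside `center +/- half_width` (pre-selection
#' of core-excited basis states).
#'
#' Configurations are deduplicated and sorted by
#' `(zeroth_order_energy, index1, index2)`, which makes the ordering stable
#' across runs.
#'
#' @param m1,m2 Validated [monomer_states()] objects for monomers 1 and 2.
#' @param approximation `"OPA"` or `"TPA"`.
#' @param window Optional `c(center, half_width)` in eV applied to core-state
#'   energies (closed interval), or the result of [select_core_window()].
#' @return An `exciton_basis` tibble with columns `index1`, `index2` (state
#'   indices into `m1`/`m2`), `energy` (zeroth-order energy, the sum of the
#'   two monomer energies), and `n_excited` (0, 1 or 2 monomers excited), with
#'   attributes `approximation` and `window`.
#' @examples
#' m <- make_toy_monomer(toy_monomer_spec(preset = "minimal-3-state", seed = 1))
#' nrow(build_basis(m, m, "OPA"))  # 5: gg, vg, cg, gv, gc
#' nrow(build_basis(m, m, "TPA"))  # 9: full 3x3 product
#' @export
build_basis <- function(m1, m2, approximation = c("TPA", "OPA"),
                        window = NULL) {
  if (length(approximation) == 1L &&
      !approximation %in% c("OPA", "TPA"))
    xs_abort(paste0("unknown approximation label: ", approximation),
             "excitonxs_format_error")
  approximation <- match.arg(approximation)
  n1 <- length(m1$energies); n2 <- length(m2$energies)
  g1 <- which(m1$manifold == "ground"); g2 <- which(m2$manifold == "ground")
  e1 <- which(m1$manifold != "ground"); e2 <- which(m2$manifold != "ground")

  pairs <- rbind(
    expand.grid(index1 = g1, index2 = g2),   # |g1 g2>
    expand.grid(index1 = e1, index2 = g2),   # |a1 g2>
    expand.grid(index1 = g1, index2 = e2)    # |g1 a2>
  )
  if (approximation == "TPA")
    pairs <- rbind(pairs, expand.grid(index1 = e1, index2 = e2))
  pairs <- unique(pairs)

  if (!is.null(window)) {
    if (is.list(window)) window <- c(window$center, window$half_width)
    if (length(window) != 2L || window[2] <= 0)
      xs_abort("`window` must be c(center, half_width) with half_width > 0",
               "excitonxs_format_error")
    keep_core <- function(m, idx) {
      core <- m$manifold[idx] == "core"
      ok <- rep(TRUE, length(idx))
      ok[core] <- abs(m$energies[idx[core]] - window[1]) <= window[2]
      ok
    }
    pairs <- pairs[keep_core(m1, pairs$index1) & keep_core(m2, pairs$index2), ]
  }
  if (nrow(pairs) == 0L)
    xs_abort("resulting exciton basis is empty", "excitonxs_validation_error")

  energy <- m1$energies[pairs$index1] + m2$energies[pairs$index2]
  n_exc <- (m1$manifold[pairs$index1] != "ground") +
           (m2$manifold[pairs$index2] != "ground")
  ord <- order(energy, pairs$index1, pairs$index2)
  out <- tibble::tibble(index1 = as.integer(pairs$index1[ord]),
                        index2 = as.integer(pairs$index2[ord]),
                        energy = energy[ord],
                        n_excited = as.integer(n_exc[ord]))
  structure(out, approximation = approximation, window = window,
            class = c("exciton_basis", class(out)))
}

#' Count exciton-basis configurations without building them
#'
#' Bookkeeping formulas for the rank of the dimer Hamiltonian block. Two
#' conventions are provided for the two-particle basis:
#' \describe{
#'   \item{`"ledger"`}{`2 * n_val * n_core + 2 * n_val` — each core excitation
#'     on either monomer paired with any of the `n_val` valence-manifold
#'     states (ground included in `n_val`) of the other monomer, plus the
#'     singly valence-excited configurations counted over all `n_val` states
#'     on each monomer. This is the convention used when quoting the rank of
#'     the RIXS-relevant block.}
#'   \item{`"full-product"`}{`(n_val + n_core)^2`, the unambiguous set size of
#'     the full product space, used by the enumeration oracle.}
#' }
#' For the one-particle basis the count is
#' `1 + 2 * (n_val - 1) + 2 * n_core`.
#'
#' @param n_val Number of valence-manifold states per monomer, ground state
#'   included (`>= 1`).
#' @param n_core Number of core-excited states per monomer (`>= 0`).
#' @param approximation `"OPA"` or `"TPA"`.
#' @param convention Counting convention for TPA, see Details.
#' @return Integer-valued count.
#' @examples
#' count_basis(102, 690, "TPA")  # 140964
#' count_basis(1, 0, "OPA")      # 1
#' @export
count_basis <- function(n_val, n_core, approximation = c("TPA", "OPA"),
                        convention = c("ledger", "full-product")) {
  approximation <- match.arg(approximation)
  convention <- match.arg(convention)
  if (n_val < 1 || n_core < 0)
    xs_abort("need n_val >= 1 and n_core >= 0", "excitonxs_format_error")
  if (approximation == "OPA")
    return(1 + 2 * (n_val - 1) + 2 * n_core)
  if (convention == "ledger")
    2 * n_val * n_core + 2 * n_val
  else
    (n_val + n_core)^2
}

#' Pre-select core-excited states inside an energy window
#'
#' Implements the core-state pre-selection used to keep the Hamiltonian block
#' tractable: only core states within `multiplier * sigma` of the excitation
#' pulse center are kept (closed interval), where `sigma` is the Gaussian
#' width of the pulse. With the default `multiplier = 5` and a 0.25 eV pulse
#' this is the `+/- 1.25` eV window.
#'
#' @param core_energies Core-state energies in eV.
#' @param center Window center (eV), typically the excitation-pulse center.
#' @param sigma Gaussian pulse width (eV), `> 0`.
#' @param multiplier Half-width in units of `sigma`, `> 0`.
#' @return A list with `kept` (integer indices into `core_energies`),
#'   `half_width` (eV), `center`, and `empty` (`TRUE`, with a warning, when no
#'   state falls inside the window; the caller decides how to proceed).
#' @examples
#' select_core_window(c(708.5, 709, 710, 711.5), 710, 0.25, 5)$kept  # 2 3
#' @export
select_core_window <- function(core_energies, center, sigma, multiplier = 5) {
  if (!is.finite(sigma) || sigma <= 0)
    xs_abort("`sigma` must be > 0", "excitonxs_format_error")
  if (multiplier <= 0)
    xs_abort("`multiplier` must be > 0", "excitonxs_format_error")
  half_width <- multiplier * sigma
  kept <- which(abs(core_energies - center) <= half_width)
  empty <- length(kept) == 0L
  if (empty) warning("core-state window is empty")
  list(kept = kept, half_width = half_width, center = center, empty = empty)
}
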