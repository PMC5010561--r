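# Monomer exchange format: versioned JSON, doubles serialized at 17
# significant digits so write/load round-trips are bit-exact.

.monomer_format <- "excitonxs-monomer"
.monomer_format_version <- 1L

#' Write a monomer state set to the exchange format
#'
#' Serializes a `monomer_states` object to the package's self-describing JSON
#' exchange schema (energies in eV, complex dipoles in atomic units stored as
#' separate real and imaginary arrays, geometry, manifold and spin labels).
#' Doubles are written with 17 significant digits, so `load_monomer()`
#' recovers the object bit-exactly.
#'
#' @param x A validated `monomer_states` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [load_monomer()]
#' @export
write_monomer <- function(x, path) {
  validate_monomer(x, hermiticity_tol = Inf)  # structural checks only
  n <- length(x$energies)
  payload <- list(
    format = .monomer_format,
    version = .monomer_format_version,
    n_states = n,
    energies_ev = x$energies,
    spin_multiplicity = x$spin,
    manifold = x$manifold,
    dipoles_au = list(re = as.vector(Re(x$dipoles)),
                      im = as.vector(Im(x$dipoles))),
    center_au = x$center,
    orientation = x$orientation,
    index_map = x$index_map
  )
  jsonlite::write_json(payload, path, digits = I(17), auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' Load a monomer state set from the exchange format
#'
#' Reads and validates a monomer exchange file written by [write_monomer()].
#' Energies are returned sorted ascending (the writer already stores them so);
#' all `monomer_states` invariants are checked, including dipole Hermiticity.
#'
#' @param path Path to an exchange-format JSON file.
#' @param hermiticity_tol Hermiticity tolerance (a.u.) forwarded to
#'   [validate_monomer()].
#' @return A validated `monomer_states` object.
#' @examples
#' m <- make_toy_monomer(toy_monomer_spec(preset = "minimal-3-state", seed = 1))
#' f <- tempfile(fileext = ".json")
#' write_monomer(m, f)
#' identical(load_monomer(f)$energies, m$energies)
#' @export
load_monomer <- function(path, hermiticity_tol = 1e-10) {
  if (!file.exists(path))
    xs_abort(paste0("file not found: ", path), "excitonxs_format_error")
  raw <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e)
                    xs_abort(paste0("not a valid JSON exchange file: ",
                                    conditionMessage(e)),
                             "excitonxs_format_error"))
  for (field in c("format", "version", "n_states", "energies_ev", "manifold",
                  "spin_multiplicity", "dipoles_au", "center_au",
                  "orientation")) {
    if (is.null(raw[[field]]))
      xs_abort(paste0("field `", field, "`: missing"),
               "excitonxs_format_error")
  }
  if (!identical(raw$format, .monomer_format))
    xs_abort(paste0("field `format`: expected '", .monomer_format, "', got '",
                    raw$format, "'"), "excitonxs_format_error")
  if (raw$version > .monomer_format_version)
    xs_abort(sprintf("field `version`: unsupported version %s", raw$version),
             "excitonxs_format_error")
  n <- as.integer(raw$n_states)
  if (length(raw$energies_ev) != n)
    xs_abort("field `energies_ev`: length disagrees with `n_states`",
             "excitonxs_format_error")
  if (length(raw$dipoles_au$re) != 3L * n * n ||
      length(raw$dipoles_au$im) != 3L * n * n)
    xs_abort("field `dipoles_au`: re/im arrays must have length 3*n_states^2",
             "excitonxs_format_error")
  d <- array(complex(real = raw$dipoles_au$re, imaginary = raw$dipoles_au$im),
             dim = c(n, n, 3L))
  x <- structure(
    list(
      energies    = as.numeric(raw$energies_ev),
      spin        = as.character(raw$spin_multiplicity),
      manifold    = as.character(raw$manifold),
      dipoles     = d,
      center      = as.numeric(raw$center_au),
      orientation = matrix(as.numeric(raw$orientation), 3L, 3L,
                           byrow = FALSE),
      index_map   = if (is.null(raw$index_map)) seq_len(n)
                    else as.integer(raw$index_map)
    ),
    class = "monomer_states"
  )
  # exchange files may legitimately store states unsorted; re-sort stably
  if (is.unsorted(x$energies)) {
    ord <- order(x$energies)
    x$energies <- x$energies[ord]
    x$spin <- x$spin[ord]
    x$manifold <- x$manifold[ord]
    x$dipoles <- x$dipoles[ord, ord, , drop = FALSE]
    x$index_map <- order(ord)
  }
  validate_monomer(x, hermiticity_tol = hermiticity_tol)
}

#' Build a monomer from a plain table of ground-state transitions
#'
#' Convenience importer for toy cases: a table with columns `energy` (eV) and
#' `dx`, `dy`, `dz` (real dipole components in a.u. for the ground-to-state
#' transition) is turned into a `monomer_states` object whose dipole matrix
#' carries only the ground-row/column entries. The first row must be the
#' ground state at zero energy with a zero (or omitted) dipole.
#'
#' @param table A data frame with columns `energy`, `dx`, `dy`, `dz`, or a
#'   path to a whitespace-separated text file with those columns.
#' @param ground_span,core_threshold Manifold classification parameters, see
#'   [classify_manifolds()].
#' @return A validated `monomer_states` object.
#' @export
monomer_from_table <- function(table, ground_span = 0.01,
                               core_threshold = 100) {
  if (is.character(table))
    table <- utils::read.table(table, header = TRUE)
  for (col in c("energy", "dx", "dy", "dz"))
    if (is.null(table[[col]]))
      xs_abort(paste0("field `", col, "`: missing column"),
               "excitonxs_format_error")
  n <- nrow(table)
  d <- array(0 + 0i, c(n, n, 3L))
  comp <- cbind(table$dx, table$dy, table$dz)
  for (k in 1:3) {
    d[1L, , k] <- comp[, k]
    d[, 1L, k] <- comp[, k]   # real table: Hermitian partner is identical
  }
  monomer_states(table$energy, dipoles = d,
                 ground_span = ground_span, core_threshold = core_threshold)
}
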