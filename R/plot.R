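#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a one-dimensional spectrum
#'
#' @param object A `spectrum_grid` (XAS or PFY).
#' @param ... Unused.
#' @return A ggplot object: intensity versus excitation energy.
#' @method autoplot spectrum_grid
#' @export
autoplot.spectrum_grid <- function(object, ...) {
  kind <- toupper(attr(object, "kind") %||% "spectrum")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$energy,
                                       y = .data$intensity)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Excitation energy (eV)",
                  y = "Intensity (arb. units)", title = kind) +
    ggplot2::theme_minimal()
}

#' Plot a RIXS map
#'
#' @param object A `rixs_map`.
#' @param ... Unused.
#' @return A ggplot object: emission x excitation intensity raster.
#' @method autoplot rixs_map
#' @export
autoplot.rixs_map <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$excitation,
                                       y = .data$emission,
                                       fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "Excitation energy (eV)",
                  y = "Emission energy (eV)", fill = "Intensity") +
    ggplot2::theme_minimal()
}

#' One-dimensional RIXS cut at fixed excitation energy
#'
#' Extracts the emission-axis cut of a RIXS map closest to the requested
#' excitation energy, as a `spectrum_grid`.
#'
#' @param map A [rixs()] result.
#' @param excitation Excitation energy (eV, rendered scale).
#' @return A `spectrum_grid` over the emission grid.
#' @export
rixs_cut <- function(map, excitation) {
  exc <- attr(map, "excitation_grid")
  ix <- which.min(abs(exc - excitation))
  spectrum_grid(attr(map, "emission_grid"), rixs_matrix(map)[ix, ],
                kind = sprintf("rixs cut @ %.2f eV", exc[ix]))
}

#' @importFrom rlang .data %||%
NULL
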