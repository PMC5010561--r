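#' Dimer geometry
#'
#' Describes the mutual arrangement of the two monomers: the center-to-center
#' separation vector `X12` (atomic units) and a rotation of monomer 2 about
#' the separation axis. [make_dimer_geometry()] places the separation along
#' the lab z axis, so `rotation_deg` rotates monomer 2's dipoles about z; in
#' the dipole approximation the geometry enters only through `X12` and the
#' orientation of the dipoles.
#'
#' @param distance Center-to-center distance in atomic units, `> 0`.
#' @param rotation_deg Rotation angle of monomer 2 about the separation axis,
#'   in degrees.
#' @return An object of class `dimer_geometry`: list with `X12` (3-vector,
#'   a.u.), `rotation` (3x3 matrix applied to monomer 2's dipoles), and
#'   `rotation_deg`.
#' @examples
#' geo <- make_dimer_geometry(7, 90)
#' geo$X12
#' @export
make_dimer_geometry <- function(distance, rotation_deg = 0) {
  if (!is.finite(distance) || distance <= 0)
    xs_abort("`distance` must be > 0", "excitonxs_format_error")
  structure(
    list(X12 = c(0, 0, distance),
         rotation = rotation_about_z(rotation_deg),
         rotation_deg = rotation_deg),
    class = "dimer_geometry"
  )
}

#' Rotation matrices about lab axes
#'
#' Active rotation matrices in degrees, used for dimer geometry and for the
#' rigid-rotation invariance checks of orientationally averaged spectra.
#'
#' @param angle_deg Rotation angle in degrees.
#' @return A 3x3 rotation matrix.
#' @export
rotation_about_z <- function(angle_deg) {
  a <- angle_deg * pi / 180
  matrix(c(cos(a), sin(a), 0,
           -sin(a), cos(a), 0,
           0, 0, 1), 3, 3)
}

#' @rdname rotation_about_z
#' @export
rotation_about_y <- function(angle_deg) {
  a <- angle_deg * pi / 180
  matrix(c(cos(a), 0, -sin(a),
           0, 1, 0,
           sin(a), 0, cos(a)), 3, 3)
}

# ZYZ Euler-angle rotation, used by the orientational-averaging quadrature.
rotation_euler_zyz <- function(alpha, beta, gamma) {
  rotation_about_z(alpha * 180 / pi) %*%
    rotation_about_y(beta * 180 / pi) %*%
    rotation_about_z(gamma * 180 / pi)
}
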