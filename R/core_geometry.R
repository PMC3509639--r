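#' Unit dipole vector from tilt and azimuth angles
#'
#' Converts spherical angles to a Cartesian unit vector using the membrane
#' frame convention: the z-axis is the membrane normal, the tilt `theta` is
#' measured from +z, and the azimuth `phi` lies in the membrane (xy) plane.
#'
#' @param theta Tilt angle in radians, in `[0, pi]`.
#' @param phi Azimuth angle in radians, in `[0, 2*pi)`.
#' @return Numeric vector `c(x, y, z)` of unit modulus,
#'   `(sin(theta)cos(phi), sin(theta)sin(phi), cos(theta))`.
#' @examples
#' unit_vector_from_angles(pi / 2, 0)  # in-plane dipole along x
#' unit_vector_from_angles(0, 1.23)    # along the membrane normal
#' @export
unit_vector_from_angles <- function(theta, phi) {
  if (!is.numeric(theta) || length(theta) != 1L || is.na(theta) ||
      theta < 0 || theta > pi) {
    stop("`theta` must be a single value in [0, pi] (radians)", call. = FALSE)
  }
  if (!is.numeric(phi) || length(phi) != 1L || is.na(phi) ||
      phi < 0 || phi >= 2 * pi) {
    stop("`phi` must be a single value in [0, 2*pi) (radians)", call. = FALSE)
  }
  st <- sin(theta)
  c(st * cos(phi), st * sin(phi), cos(theta))
}

#' Orientation factor for a single donor-acceptor pair
#'
#' Evaluates the FRET orientation factor
#' \deqn{\kappa^2 = (u_D \cdot u_A - 3 (\hat r \cdot u_D)(\hat r \cdot u_A))^2}
#' from the donor and acceptor transition dipole unit vectors and the vector
#' separating their centres.  The value lies in `[0, 4]`: 4 for collinear
#' dipoles along the separation axis, 1 for parallel dipoles perpendicular to
#' it, 0 for mutually orthogonal arrangements.  Dipoles are headless axes:
#' flipping the sign of either vector leaves the result unchanged, as does
#' exchanging donor and acceptor or reversing the separation vector.
#'
#' @param u_d,u_a Numeric length-3 unit vectors along the donor and acceptor
#'   transition dipoles (checked to unit modulus within `1e-12`).
#' @param sep Numeric length-3 separation vector (nm); must have nonzero
#'   modulus.
#' @return The dimensionless orientation factor, a single number in `[0, 4]`.
#' @examples
#' kappa_squared(c(1, 0, 0), c(1, 0, 0), c(1, 0, 0))  # 4
#' kappa_squared(c(0, 0, 1), c(0, 0, 1), c(1, 0, 0))  # 1
#' kappa_squared(c(0, 0, 1), c(0, 1, 0), c(1, 0, 0))  # 0
#' @export
kappa_squared <- function(u_d, u_a, sep) {
  check_unit <- function(u, name) {
    if (!is.numeric(u) || length(u) != 3L || anyNA(u)) {
      stop(sprintf("`%s` must be a numeric length-3 vector", name),
           call. = FALSE)
    }
    if (abs(sum(u^2) - 1) > 1e-12) {
      stop(sprintf("`%s` must have unit modulus (|1 - |u|^2| <= 1e-12)", name),
           call. = FALSE)
    }
  }
  check_unit(u_d, "u_d")
  check_unit(u_a, "u_a")
  if (!is.numeric(sep) || length(sep) != 3L || anyNA(sep)) {
    stop("`sep` must be a numeric length-3 vector", call. = FALSE)
  }
  r2 <- sum(sep^2)
  if (r2 == 0) {
    stop("degenerate geometry: separation vector has zero length",
         call. = FALSE)
  }
  r_hat <- sep / sqrt(r2)
  (sum(u_d * u_a) - 3 * sum(r_hat * u_d) * sum(r_hat * u_a))^2
}

# Vectorized kernel used by the simulation engines.  All arguments are
# equal-length numeric vectors of Cartesian components; (sx, sy, sz) need not
# be normalized.  Returns kappa^2 per pair.
kappa2_vec <- function(udx, udy, udz, uax, uay, uaz, sx, sy, sz) {
  r <- sqrt(sx * sx + sy * sy + sz * sz)
  dot <- udx * uax + udy * uay + udz * uaz
  dd <- (sx * udx + sy * udy + sz * udz) / r
  da <- (sx * uax + sy * uay + sz * uaz) / r
  (dot - 3 * dd * da)^2
}
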