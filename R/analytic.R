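#' Isotropic kappa-squared probability density
#'
#' Closed-form probability density of the orientation factor when both
#' dipoles are oriented isotropically (dynamic limit):
#' \deqn{p(\kappa^2) = \frac{\ln(2+\sqrt 3)}{2\sqrt3\sqrt{\kappa^2}},
#'   \quad 0 < \kappa^2 \le 1,}
#' \deqn{p(\kappa^2) = \frac{1}{2\sqrt3\sqrt{\kappa^2}}
#'   \ln\frac{2+\sqrt 3}{\sqrt{\kappa^2}+\sqrt{\kappa^2-1}},
#'   \quad 1 \le \kappa^2 \le 4.}
#' The density has an integrable singularity at 0, is continuous at
#' `kappa2 = 1`, integrates to 1 and has mean 2/3.
#'
#' @param kappa2 Numeric vector of orientation-factor values in `(0, 4]`.
#' @return Density values at `kappa2`.
#' @examples
#' integrate(isotropic_pdf, 0, 4)           # 1
#' integrate(function(x) x * isotropic_pdf(x), 0, 4)  # 2/3
#' @export
isotropic_pdf <- function(kappa2) {
  if (!is.numeric(kappa2) || anyNA(kappa2) ||
      any(kappa2 <= 0 | kappa2 > 4)) {
    stop("`kappa2` must lie in (0, 4]", call. = FALSE)
  }
  s3 <- sqrt(3)
  rt <- sqrt(kappa2)
  out <- numeric(length(kappa2))
  lo <- kappa2 <= 1
  out[lo] <- log(2 + s3) / (2 * s3 * rt[lo])
  hi <- !lo
  out[hi] <- log((2 + s3) / (rt[hi] + sqrt(kappa2[hi] - 1))) /
    (2 * s3 * rt[hi])
  out
}

#' Average kappa-squared for identically oriented coplanar dipoles
#'
#' Knoester-van Himbergen closed form for two-dimensional FRET between
#' donors and acceptors whose transition dipoles all make the same fixed
#' tilt `theta` with the membrane normal:
#' \deqn{\langle\kappa^2\rangle = 2/3 - (2/3) S + S^2, \qquad
#'   S = (3\cos^2\theta - 1)/2,}
#' where `S` is the second-rank orientational order parameter
#' `P2(cos(theta))`.  Applies with no orientational heterogeneity
#' (`sigma = 0`), for which `<cos^2(theta)> = cos^2(theta)`.
#'
#' @param theta Tilt angle(s), degrees in `[0, 180]`.
#' @return Average orientation factor(s); ranges from 5/9 (at 41.81 or
#'   138.19 degrees) to 1.25 (at 90 degrees).
#' @examples
#' knoester_mean(c(0, 41.81, 54.74, 90))
#' @export
knoester_mean <- function(theta) {
  if (!is.numeric(theta) || anyNA(theta) || any(theta < 0 | theta > 180)) {
    stop("`theta` must lie in [0, 180] degrees", call. = FALSE)
  }
  s <- (3 * cos(theta * pi / 180)^2 - 1) / 2
  2 / 3 - 2 / 3 * s + s^2
}

#' Special tilt angles of the identically-oriented planar average
#'
#' The angles at which the Knoester-van Himbergen average attains its
#' extrema, and the four tilts at which it equals the isotropic value 2/3
#' (`S = 0`, the magic angle and its supplement, and `S = 2/3`).
#'
#' @return A data frame with columns `theta_deg`, `mean` and `type`
#'   (`"extremum"` or `"isotropic-crossing"`), exact to machine precision.
#' @examples
#' knoester_special_angles()
#' @export
knoester_special_angles <- function() {
  deg <- function(x) acos(sqrt(x)) * 180 / pi
  up <- function(x) 180 - x
  ang <- c(0, deg(5 / 9), 90, up(deg(5 / 9)), 180,          # extrema
           deg(7 / 9), deg(1 / 3), up(deg(1 / 3)), up(deg(7 / 9)))
  data.frame(
    theta_deg = ang,
    mean = knoester_mean(ang),
    type = rep(c("extremum", "isotropic-crossing"), c(5, 4))
  )
}
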