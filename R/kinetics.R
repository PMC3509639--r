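#' Forster radius from photophysical parameters
#'
#' \deqn{R_0 = 0.02108\,[\kappa^2\,\Phi_0\,n^{-4}\,J]^{1/6}\ \mathrm{nm}}
#' where `J` is the overlap integral between the area-normalized donor
#' emission spectrum and the acceptor molar absorption spectrum, weighted by
#' the fourth power of the wavelength.  The numeric constant assumes nm
#' units for wavelength and radius and M^-1 cm^-1 for the absorption
#' coefficient.
#'
#' @param kappa2 Orientation factor (dimensionless, `[0, 4]`); 2/3 in the
#'   dynamic isotropic limit.
#' @param quantum_yield Donor quantum yield in the absence of acceptor,
#'   in `(0, 1]`.
#' @param ref_index Refractive index of the medium (`> 0`).
#' @param overlap Overlap integral `J`, nm^4 M^-1 cm^-1 (`>= 0`).
#' @return Forster radius in nm.
#' @examples
#' forster_radius(2 / 3, 0.5, 1.4, 2.5e14)
#' @export
forster_radius <- function(kappa2, quantum_yield, ref_index, overlap) {
  if (!is.numeric(kappa2) || anyNA(kappa2) || any(kappa2 < 0 | kappa2 > 4)) {
    stop("`kappa2` must lie in [0, 4]", call. = FALSE)
  }
  if (!is.numeric(quantum_yield) || anyNA(quantum_yield) ||
      any(quantum_yield <= 0 | quantum_yield > 1)) {
    stop("`quantum_yield` must lie in (0, 1]", call. = FALSE)
  }
  if (!is.numeric(ref_index) || anyNA(ref_index) || any(ref_index <= 0)) {
    stop("`ref_index` must be positive", call. = FALSE)
  }
  if (!is.numeric(overlap) || anyNA(overlap) || any(overlap < 0)) {
    stop("`overlap` must be nonnegative", call. = FALSE)
  }
  0.02108 * (kappa2 * quantum_yield * ref_index^-4 * overlap)^(1 / 6)
}

#' Dimensionless parameters of a planar FRET system
#'
#' Bundles the three dimensionless parameters governing the planar donor
#' decay in reduced time `zeta = t / tau0`:
#' `alpha = R0bar / Re` (Forster radius at `kappa^2 = 2/3` over the
#' exclusion distance), `beta = (3/2) <kappa^2>` (so `beta = 1` in the
#' isotropic limit), and the reduced acceptor density
#' `sigma_c = pi * R0bar^2 * c` (expected acceptors within a circle of
#' radius `R0bar`).
#'
#' @param alpha Ratio `R0bar / Re` (`> 0`).
#' @param kappa2 Average orientation factor; stored as `beta = 1.5 * kappa2`.
#' @param sigma_c Reduced acceptor density (`>= 0`).
#' @return An object of class `fret_spec` with fields `alpha`, `beta`,
#'   `sigma_c`.
#' @examples
#' fret_spec(alpha = 0.5, kappa2 = 1.25, sigma_c = 2)
#' @export
fret_spec <- function(alpha, kappa2 = 2 / 3, sigma_c = 0) {
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) || alpha <= 0) {
    stop("`alpha` must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(kappa2) || length(kappa2) != 1L || is.na(kappa2) ||
      kappa2 < 0 || kappa2 > 4) {
    stop("`kappa2` must lie in [0, 4]", call. = FALSE)
  }
  if (!is.numeric(sigma_c) || length(sigma_c) != 1L || is.na(sigma_c) ||
      sigma_c < 0) {
    stop("`sigma_c` must be a single nonnegative number", call. = FALSE)
  }
  structure(list(alpha = alpha, beta = 1.5 * kappa2, sigma_c = sigma_c),
            class = "fret_spec")
}

# Lower (unnormalized) incomplete gamma: integral of t^(s-1) e^-t on [0, x].
lower_inc_gamma <- function(s, x) gamma(s) * stats::pgamma(x, s)

#' Reduced-time donor decay in the presence of a plane of acceptors
#'
#' The donor survival function in reduced time `zeta = t / tau0` for a
#' uniform plane of acceptors no closer than the exclusion distance:
#' \deqn{i_{DA}(\zeta) = e^{-\zeta}\exp\Big\{-\beta^{1/3}\sigma_c\Big(
#'   \gamma[\tfrac23, \beta\alpha^6\zeta]\,\zeta^{1/3}
#'   - \frac{1 - e^{-\beta\alpha^6\zeta}}{\beta^{1/3}\alpha^2}\Big)\Big\}}
#' with `gamma` the lower (unnormalized) incomplete gamma function.  As
#' `alpha` grows (vanishing exclusion distance) this approaches the
#' classical planar decay `exp(-zeta) exp(-sigma_c beta^{1/3}
#' Gamma(2/3) zeta^{1/3})`; at `sigma_c = 0` it is the unquenched
#' exponential.
#'
#' @param zeta Reduced time(s), `>= 0`.
#' @param spec A [fret_spec()].
#' @return Donor intensity fraction(s) in `(0, 1]`.
#' @examples
#' donor_decay_reduced(c(0, 0.5, 1), fret_spec(2, 2 / 3, 1))
#' @export
donor_decay_reduced <- function(zeta, spec) {
  stopifnot(inherits(spec, "fret_spec"))
  if (!is.numeric(zeta) || anyNA(zeta) || any(zeta < 0)) {
    stop("`zeta` must be nonnegative", call. = FALSE)
  }
  a <- spec$alpha
  b <- spec$beta
  s <- spec$sigma_c
  if (s == 0 || b == 0) return(exp(-zeta))
  x <- b * a^6 * zeta
  bracket <- lower_inc_gamma(2 / 3, x) * zeta^(1 / 3) -
    (1 - exp(-x)) / (b^(1 / 3) * a^2)
  exp(-zeta) * exp(-b^(1 / 3) * s * bracket)
}

#' Donor decay in laboratory units
#'
#' Thin wrapper around [donor_decay_reduced()] converting dimensional
#' parameters to the reduced form: `zeta = t / tau0`,
#' `alpha = r0bar / re`, `beta = 1.5 * kappa2`,
#' `sigma_c = pi * r0bar^2 * c_acceptor`.
#'
#' @param t Time(s), same units as `tau0`.
#' @param tau0 Donor lifetime without acceptor.
#' @param r0bar Forster radius computed with `kappa^2 = 2/3`, nm.
#' @param re Exclusion distance, nm (`> 0`).
#' @param c_acceptor Acceptors per nm^2.
#' @param kappa2 Average orientation factor used for the actual rate.
#' @return Donor intensity fraction(s).
#' @export
donor_decay <- function(t, tau0, r0bar, re, c_acceptor, kappa2 = 2 / 3) {
  if (!is.numeric(tau0) || tau0 <= 0) stop("`tau0` must be positive",
                                           call. = FALSE)
  if (!is.numeric(re) || re <= 0) stop("`re` must be positive", call. = FALSE)
  spec <- fret_spec(alpha = r0bar / re, kappa2 = kappa2,
                    sigma_c = pi * r0bar^2 * c_acceptor)
  donor_decay_reduced(t / tau0, spec)
}

#' FRET efficiency of a planar system
#'
#' \deqn{E = 1 - \int_0^\infty i_{DA}(\zeta)\,d\zeta}
#' (the unquenched decay integrates to 1 in reduced time).  Computed by
#' adaptive quadrature to absolute tolerance `1e-8`.
#'
#' @param spec A [fret_spec()].
#' @return Efficiency in `[0, 1]`.
#' @examples
#' fret_efficiency(fret_spec(alpha = 2, kappa2 = 2 / 3, sigma_c = 1))
#' @export
fret_efficiency <- function(spec) {
  stopifnot(inherits(spec, "fret_spec"))
  if (spec$sigma_c == 0) return(0)
  q <- stats::integrate(function(z) donor_decay_reduced(z, spec),
                        lower = 0, upper = Inf,
                        rel.tol = 1e-10, abs.tol = 1e-8,
                        subdivisions = 500L)
  if (q$message != "OK") {
    stop("efficiency quadrature did not converge: ", q$message,
         call. = FALSE)
  }
  min(max(1 - q$value, 0), 1)
}

#' Universal efficiency-versus-density curve
#'
#' Evaluates the FRET efficiency over a grid of reduced acceptor densities
#' at fixed `alpha` and average orientation factor, producing one of the
#' universal `E` vs `sigma_c` curves.
#'
#' @param alpha Ratio `R0bar / Re`.
#' @param kappa2 Average orientation factor.
#' @param sigma_grid Nondecreasing vector of nonnegative reduced densities.
#' @return A data frame with columns `sigma_c` and `efficiency`
#'   (nondecreasing).
#' @examples
#' efficiency_curve(0.5, 1.25, seq(0, 5, by = 1))
#' @export
efficiency_curve <- function(alpha, kappa2, sigma_grid) {
  if (!is.numeric(sigma_grid) || anyNA(sigma_grid) || any(sigma_grid < 0) ||
      is.unsorted(sigma_grid)) {
    stop("`sigma_grid` must be nonnegative and ascending", call. = FALSE)
  }
  eff <- vapply(sigma_grid, function(s) {
    fret_efficiency(fret_spec(alpha, kappa2, s))
  }, numeric(1))
  data.frame(sigma_c = sigma_grid, efficiency = eff)
}
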