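# Independent reference implementations used as oracles.  These deliberately
# avoid the package's vectorized code paths.

# kappa^2 via the angle form (cos psi_T - 3 cos psi_D cos psi_A)^2, with the
# angles recovered through arccosines.
kappa2_angle_ref <- function(u_d, u_a, sep) {
  r <- sep / sqrt(sum(sep^2))
  clamp <- function(x) max(-1, min(1, x))
  psi_t <- acos(clamp(sum(u_d * u_a)))
  psi_d <- acos(clamp(sum(r * u_d)))
  psi_a <- acos(clamp(sum(r * u_a)))
  (cos(psi_t) - 3 * cos(psi_d) * cos(psi_a))^2
}

# Scalar loop over a per-pair table (as returned by return_pairs = TRUE),
# recomputing kappa^2 one pair at a time from first principles.
kappa2_pairs_ref <- function(pairs) {
  vapply(seq_len(nrow(pairs)), function(i) {
    ud <- unit_vector_from_angles(pairs$theta_d[i], pairs$phi_d[i])
    ua <- unit_vector_from_angles(pairs$theta_a[i], pairs$phi_a[i])
    sep <- c(pairs$ax[i] - pairs$dx[i], pairs$ay[i] - pairs$dy[i], pairs$z[i])
    kappa_squared(ud, ua, sep)
  }, numeric(1))
}

# Random dipole axes, uniform on the sphere.
random_unit_vectors <- function(n) {
  ct <- stats::runif(n, -1, 1)
  ph <- stats::runif(n, 0, 2 * pi)
  st <- sqrt(1 - ct^2)
  cbind(st * cos(ph), st * sin(ph), ct)
}

# Fixed-grid Simpson integral of the reduced donor decay on [0, zmax];
# the integrand is bounded by exp(-z), so the truncation error at zmax = 40
# is below 1e-17.
simpson_decay_integral <- function(spec, zmax = 40, n = 200001) {
  z <- seq(0, zmax, length.out = n)
  f <- donor_decay_reduced(z, spec)
  h <- z[2] - z[1]
  h / 3 * (f[1] + f[n] + 4 * sum(f[seq(2, n - 1, 2)]) +
             2 * sum(f[seq(3, n - 2, 2)]))
}

# Probabilities of the truncated Normal(mu, sigma) on [-1, 1] over bins.
trunc_normal_bin_probs <- function(mu, sigma, edges) {
  z <- stats::pnorm(edges, mu, sigma)
  (z[-1] - z[-length(z)]) /
    (stats::pnorm(1, mu, sigma) - stats::pnorm(-1, mu, sigma))
}

# Expected bin probabilities of the closed-form isotropic kappa^2 density.
isotropic_bin_probs <- function(edges) {
  vapply(seq_len(length(edges) - 1L), function(i) {
    stats::integrate(isotropic_pdf, edges[i] + 1e-12, edges[i + 1],
                     rel.tol = 1e-10)$value
  }, numeric(1))
}

magic_angle_deg <- acos(sqrt(1 / 3)) * 180 / pi
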