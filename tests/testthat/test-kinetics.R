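test_that("forster_radius follows the one-sixth-power law", {
  expect_equal(forster_radius(2 / 3, 0.5, 1.4, 0), 0)
  r1 <- forster_radius(1, 0.5, 1.4, 2.5e14)
  r2 <- forster_radius(2, 0.5, 1.4, 2.5e14)
  expect_equal(r2 / r1, 2^(1 / 6), tolerance = 1e-12)
  # frozen single-expression oracle
  expect_equal(forster_radius(2 / 3, 0.5, 1.4, 2.5e14), 3.520371,
               tolerance = 1e-6)
  expect_error(forster_radius(5, 0.5, 1.4, 1), "0, 4")
  expect_error(forster_radius(1, 0, 1.4, 1), "quantum_yield")
  expect_error(forster_radius(1, 0.5, -1, 1), "ref_index")
})

test_that("fret_spec validates and stores beta = 1.5 kappa2", {
  s <- fret_spec(alpha = 2, kappa2 = 1.25, sigma_c = 3)
  expect_equal(s$beta, 1.875)
  expect_error(fret_spec(0, 1, 1), "alpha")
  expect_error(fret_spec(1, 5, 1), "kappa2")
  expect_error(fret_spec(1, 1, -1), "sigma_c")
})

test_that("the reduced decay has the right limits", {
  s <- fret_spec(alpha = 2, kappa2 = 2 / 3, sigma_c = 1.5)
  expect_identical(donor_decay_reduced(0, s), 1)
  z <- seq(0, 5, by = 0.25)
  s0 <- fret_spec(alpha = 2, kappa2 = 2 / 3, sigma_c = 0)
  expect_equal(donor_decay_reduced(z, s0), exp(-z))
  # vanishing exclusion distance: classical planar decay with Gamma(2/3)
  sl <- fret_spec(alpha = 1e6, kappa2 = 2 / 3, sigma_c = 1)
  lim <- exp(-1) * exp(-1 * gamma(2 / 3) * 1)
  expect_equal(donor_decay_reduced(1, sl), lim, tolerance = 1e-6)
  expect_error(donor_decay_reduced(-0.1, s), "nonnegative")
})

test_that("the decay is bounded and monotone over a parameter lattice", {
  z <- seq(0, 10, by = 0.05)
  for (a in c(0.5, 1, 2, 5)) {
    for (b in c(0.45, 1, 1.875)) {
      for (s in c(0.5, 2, 10)) {
        spec <- fret_spec(alpha = a, kappa2 = b / 1.5, sigma_c = s)
        i <- donor_decay_reduced(z, spec)
        expect_true(all(i > 0 & i <= 1))
        expect_true(all(i <= exp(-z) * exp(s / a^2) + 1e-12))
        expect_true(all(diff(i) <= 1e-12))
      }
    }
  }
})

test_that("dimensional decay wraps the reduced form consistently", {
  i1 <- donor_decay(t = 3, tau0 = 2, r0bar = 5, re = 2.5, c_acceptor = 0.02,
                    kappa2 = 0.8)
  i2 <- donor_decay_reduced(1.5, fret_spec(alpha = 2, kappa2 = 0.8,
                                           sigma_c = pi * 25 * 0.02))
  expect_identical(i1, i2)
  expect_error(donor_decay(1, 0, 5, 2.5, 0.02), "tau0")
  expect_error(donor_decay(1, 2, 5, 0, 0.02), "re")
})

test_that("efficiency matches a fixed-grid Simpson oracle", {
  expect_identical(fret_efficiency(fret_spec(1, 2 / 3, 0)), 0)
  # frozen oracle value at alpha = 2, beta = 1, sigma_c = 1
  expect_equal(fret_efficiency(fret_spec(2, 2 / 3, 1)), 0.5800681,
               tolerance = 1e-5)
  set.seed(71)
  for (i in 1:20) {
    spec <- fret_spec(alpha = runif(1, 0.5, 5),
                      kappa2 = runif(1, 0.3, 1.25),
                      sigma_c = runif(1, 0.2, 5))
    e_pkg <- fret_efficiency(spec)
    e_ref <- 1 - simpson_decay_integral(spec)
    expect_equal(e_pkg, e_ref, tolerance = 1e-6)
  }
})

test_that("efficiency increases with density and orientation factor", {
  for (a in c(0.5, 1, 2, 5)) {
    e_sigma <- efficiency_curve(a, 2 / 3, c(0, 0.5, 1, 2, 5, 10))$efficiency
    expect_true(all(diff(e_sigma) > 0))
    expect_identical(e_sigma[1], 0)
    expect_true(all(e_sigma >= 0 & e_sigma <= 1))
    for (s in c(0.5, 2, 10)) {
      e_beta <- vapply(c(0.30, 0.50, 2 / 3, 0.80, 1.25), function(k2) {
        fret_efficiency(fret_spec(a, k2, s))
      }, numeric(1))
      expect_true(all(diff(e_beta) > 0))
    }
  }
  expect_error(efficiency_curve(1, 2 / 3, c(3, 1)), "ascending")
})

test_that("high-kappa2 transfer beats low-kappa2 by > 3x at alpha = 0.5", {
  for (s in 1:5) {
    e_hi <- fret_efficiency(fret_spec(0.5, 1.25, s))
    e_lo <- fret_efficiency(fret_spec(0.5, 0.30, s))
    expect_gt(e_hi / e_lo, 3)
  }
})
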