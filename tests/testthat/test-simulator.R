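test_that("dipoles along the normal give the invariant kappa^2 = 1 in-plane", {
  g <- geometry_config(n = 1e4, h = 0, l = 100)
  r <- simulate_unweighted(angular_spec(0, 0), angular_spec(0, 0), g,
                           seed = 31, return_pairs = TRUE)
  expect_identical(unique(r$pairs$kappa2), 1)
  expect_identical(r$mean_unweighted, 1)
  expect_identical(r$max_kappa2, 1)
})

test_that("magic-angle coplanar runs stay below the 25/9 support cutoff", {
  g <- geometry_config(n = 1e5, h = 0)
  r <- simulate_unweighted(angular_spec(magic_angle_deg, 0),
                           angular_spec(magic_angle_deg, 0), g, seed = 32)
  expect_lte(r$max_kappa2, 25 / 9)
  se <- r$sd_kappa2 / sqrt(g$n)
  expect_lt(abs(r$mean_unweighted - 2 / 3), 4 * se)
})

test_that("in-plane identical dipoles average 1.25 in the plane", {
  g <- geometry_config(n = 1e5, h = 0)
  r <- simulate_unweighted(angular_spec(90, 0), angular_spec(90, 0), g,
                           seed = 33)
  se <- r$sd_kappa2 / sqrt(g$n)
  expect_lt(abs(r$mean_unweighted - 1.25), 4 * se)
})

test_that("histogram densities integrate to one", {
  g <- geometry_config(n = 1e5, h = 0, n_bins = 73)
  r <- simulate_unweighted(angular_spec(60, 0.2), angular_spec(120, 0.1), g,
                           seed = 34)
  expect_equal(sum(r$density * diff(r$bin_edges)), 1, tolerance = 1e-9)
  expect_true(all(r$density >= 0))
  expect_equal(sum(r$theta_d_hist$density * pi / g$n_bins), 1,
               tolerance = 1e-9)
})

test_that("vectorized engine matches a scalar per-pair reference", {
  g <- geometry_config(n = 1e3, h = 1.3, l = 10)
  r <- simulate_unweighted(angular_spec(60, 0.2), angular_spec(120, 0.35), g,
                           seed = 35, return_pairs = TRUE)
  ref <- kappa2_pairs_ref(r$pairs)
  expect_equal(r$pairs$kappa2, ref, tolerance = 1e-12)
  expect_equal(r$mean_unweighted, mean(ref), tolerance = 1e-12)
})

test_that("coplanar distributions are independent of the system size", {
  means <- ses <- numeric(0)
  for (l in c(1, 2, 4, 8, 100)) {
    g <- geometry_config(n = 1e5, h = 0, l = l)
    r <- simulate_unweighted(angular_spec(90, 0), angular_spec(90, 0), g,
                             seed = 36)
    means <- c(means, r$mean_unweighted)
    ses <- c(ses, r$sd_kappa2 / sqrt(g$n))
  }
  expect_true(all(abs(means - mean(means)) < 3 * ses))
})

test_that("parallel-plane means approach the coplanar value as l grows", {
  means <- ses <- numeric(0)
  for (l in c(2, 8, 100, 1000)) {
    r <- simulate_unweighted(angular_spec(90, 0), angular_spec(90, 0),
                             geometry_config(n = 1e5, h = 2, l = l),
                             seed = 37)
    means <- c(means, r$mean_unweighted)
    ses <- c(ses, r$sd_kappa2 / sqrt(1e5))
  }
  # constrained small boxes force out-of-plane separations: mean far below
  expect_gt(abs(means[1] - 1.25), 100 * ses[1])
  # monotone approach, converged within MC error once l >> h
  expect_true(all(diff(abs(means - 1.25)) < 0))
  expect_lt(abs(means[4] - 1.25), 4 * ses[4])
})

test_that("donor/acceptor exchange and tilt mirroring leave means unchanged", {
  g <- geometry_config(n = 2e5, h = 0)
  d <- angular_spec(60, 0.2)
  a <- angular_spec(120, 0.1)
  r1 <- simulate_unweighted(d, a, g, seed = 38)
  r2 <- simulate_unweighted(a, d, g, seed = 39)
  se <- sqrt(2) * r1$sd_kappa2 / sqrt(g$n)
  expect_lt(abs(r1$mean_unweighted - r2$mean_unweighted), 4 * se)
  r3 <- simulate_unweighted(angular_spec(120, 0.2), angular_spec(60, 0.1),
                            g, seed = 40)
  expect_lt(abs(r1$mean_unweighted - r3$mean_unweighted), 4 * se)
})

test_that("slab acceptors with near-isotropic dipoles give 2/3", {
  g <- geometry_config(n = 1e6, slab_zmax = 5, l = 100)
  r <- simulate_unweighted_slab(angular_spec(90, 30), angular_spec(90, 30),
                                g, seed = 41)
  expect_lt(abs(r$mean_unweighted - 2 / 3), 0.005)
})

test_that("slab with vanishing thickness reduces to the coplanar run", {
  d <- angular_spec(90, 0.2)
  a <- angular_spec(60, 0.2)
  r_slab <- simulate_unweighted_slab(d, a,
                                     geometry_config(n = 2e5,
                                                     slab_zmax = 1e-9),
                                     seed = 42)
  r_flat <- simulate_unweighted(d, a, geometry_config(n = 2e5, h = 0),
                                seed = 43)
  se <- sqrt(2) * r_flat$sd_kappa2 / sqrt(2e5)
  expect_lt(abs(r_slab$mean_unweighted - r_flat$mean_unweighted), 4 * se)
})

test_that("aligned dipoles in a thick slab exceed the in-plane invariant", {
  # independent brute-force oracle at these parameters gives 1.0145
  g <- geometry_config(n = 1e6, slab_zmax = 2, l = 2)
  r <- simulate_unweighted_slab(angular_spec(0, 0), angular_spec(0, 0), g,
                                seed = 44)
  expect_gt(r$mean_unweighted, 1)
  expect_equal(r$mean_unweighted, 1.0145, tolerance = 0.01)
})

test_that("weighted mean equals unweighted when all separations coincide", {
  # l tiny against h: every pair distance is h to one part in 1e12, so the
  # R^-6 weights are constant
  g <- geometry_config(n = 1e5, h1 = 2, re1 = 0, l = 1e-6)
  r <- simulate_weighted(angular_spec(60, 0.2), angular_spec(120, 0.35), g,
                         seed = 45)
  expect_equal(r$mean_weighted, r$mean_unweighted, tolerance = 1e-6)
})

test_that("weighted runs validate their geometry", {
  d <- angular_spec(90, 0)
  expect_error(
    simulate_weighted(d, d, geometry_config(n = 100, h1 = 0, re1 = 0)),
    "re1")
  expect_error(
    simulate_weighted(d, d, geometry_config(n = 100, h = 0)),
    "h1")
  expect_error(
    simulate_weighted(d, d,
                      geometry_config(n = 100, h1 = 0, re1 = 5, l = 1),
                      seed = 46),
    "infeasible")
})

test_that("weighted pooling is consistent with the per-plane partial sums", {
  g <- geometry_config(n = 5e4, h1 = 0, h2 = 2, re1 = 0.8, re2 = 0.8)
  r <- simulate_weighted(angular_spec(90, 0), angular_spec(90, 0), g,
                         seed = 47)
  p1 <- r$planes$plane1
  p2 <- r$planes$plane2
  expect_equal(r$mean_weighted,
               (p1$sum_kw + p2$sum_kw) / (p1$sum_w + p2$sum_w),
               tolerance = 1e-12)
  expect_gte(r$mean_weighted, 0)
  expect_lte(r$mean_weighted, 4)
  # exclusion honoured: no pair closer than re contributes a larger weight
  expect_lte(max(p1$sum_w, p2$sum_w) / g$n, 0.8^-6)
})

test_that("exclusion distances are enforced on the 3D separation", {
  g <- geometry_config(n = 2e4, h1 = 0, re1 = 0.8, l = 5)
  r <- simulate_weighted(angular_spec(90, 3), angular_spec(90, 3), g,
                         seed = 48, return_pairs = TRUE)
  expect_gte(min(r$pairs$r), 0.8)
})

test_that("repeat_runs summarizes seeded repeats correctly", {
  g <- geometry_config(n = 1e4, h = 0)
  d <- angular_spec(90, 30)
  s1 <- repeat_runs(simulate_unweighted, d, d, g, n_repeats = 3,
                    base_seed = 49)
  s2 <- repeat_runs(simulate_unweighted, d, d, g, n_repeats = 3,
                    base_seed = 49)
  expect_identical(s1$means, s2$means)
  expect_equal(s1$grand_mean, mean(s1$means))
  # identical seeds forced: zero spread
  s3 <- repeat_runs(simulate_unweighted, d, d, g, seeds = c(7, 7))
  expect_identical(s3$std_dev, 0)
  expect_error(repeat_runs(simulate_unweighted, d, d, g, n_repeats = 1),
               "at least 2")
})

test_that("repeated near-isotropic runs bracket the isotropic mean", {
  g <- geometry_config(n = 1e5, h = 0)
  d <- angular_spec(90, 30)
  s <- repeat_runs(simulate_unweighted, d, d, g, n_repeats = 10,
                   base_seed = 50)
  expect_lt(abs(s$grand_mean - 2 / 3), 3 * s$std_dev / sqrt(10))
})

test_that("geometry_config rejects invalid parameters", {
  expect_error(geometry_config(l = 0), "l")
  expect_error(geometry_config(n = 0), "n")
  expect_error(geometry_config(h = -1), "h")
  expect_error(geometry_config(n_bins = 0), "n_bins")
  expect_error(geometry_config(slab_zmax = 0), "slab_zmax")
})
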