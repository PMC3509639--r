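#' Geometry of a planar donor/acceptor simulation
#'
#' Collects the spatial parameters of a run.  Donors occupy the plane
#' `z = 0` of a square of side `l`; acceptors occupy a parallel plane (or
#' slab).  Unweighted runs use a single acceptor plane at distance `h`;
#' distance-weighted runs use one or two acceptor planes at distances `h1`
#' and `h2` (the two bilayer leaflets) with per-plane exclusion distances
#' `re1`, `re2` below which donor-acceptor pairs are re-placed.
#'
#' @param l Square side length, nm (`> 0`).  The default 100 nm makes edge
#'   effects negligible for nanometre-scale transfer.
#' @param n Donor-acceptor pairs per run (per plane, for weighted runs).
#' @param h Donor-acceptor interplanar distance for unweighted runs, nm.
#' @param h1,h2 Interplanar distances of the first and second acceptor
#'   plane for weighted runs, nm.  `h2 = NULL` restricts the weighted run to
#'   a single plane.
#' @param re1,re2 Exclusion distances (minimum 3D donor-acceptor
#'   separation), nm.  A coplanar weighted plane (`h = 0`) requires a
#'   positive exclusion distance, otherwise the `R^-6` weight diverges.
#' @param slab_zmax If set, acceptor `z` is uniform on `[0, slab_zmax]`
#'   instead of fixed (3D slab variant of the unweighted run).
#' @param n_bins Number of equal-width histogram bins over `[0, 4]`.
#' @param seed Default RNG seed for runs using this geometry (optional).
#' @return An object of class `geometry_config`.
#' @examples
#' geometry_config(l = 100, n = 1e5, h = 0)
#' geometry_config(n = 1e5, h1 = 0, h2 = 2, re1 = 0.8, re2 = 0.8)
#' @export
geometry_config <- function(l = 100, n = 1e6, h = 0, h1 = NULL, h2 = NULL,
                            re1 = 0, re2 = 0, slab_zmax = NULL,
                            n_bins = 100, seed = NULL) {
  chk_num <- function(x, name, min = 0, strict = FALSE) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) ||
        (strict && x <= min) || (!strict && x < min)) {
      stop(sprintf("`%s` must be a single number %s %g", name,
                   if (strict) ">" else ">=", min), call. = FALSE)
    }
    as.numeric(x)
  }
  l <- chk_num(l, "l", 0, strict = TRUE)
  n <- chk_num(n, "n", 1)
  h <- chk_num(h, "h", 0)
  if (!is.null(h1)) h1 <- chk_num(h1, "h1", 0)
  if (!is.null(h2)) h2 <- chk_num(h2, "h2", 0)
  re1 <- chk_num(re1, "re1", 0)
  re2 <- chk_num(re2, "re2", 0)
  if (!is.null(slab_zmax)) slab_zmax <- chk_num(slab_zmax, "slab_zmax", 0,
                                                strict = TRUE)
  n_bins <- as.integer(chk_num(n_bins, "n_bins", 1))
  if (!is.null(seed)) seed <- as.integer(seed)
  structure(
    list(l = l, n = n, h = h, h1 = h1, h2 = h2, re1 = re1, re2 = re2,
         slab_zmax = slab_zmax, n_bins = n_bins, seed = seed),
    class = "geometry_config"
  )
}

#' @export
print.geometry_config <- function(x, ...) {
  cat(sprintf("<geometry_config> l = %g nm, n = %g pairs, n_bins = %d\n",
              x$l, x$n, x$n_bins))
  if (!is.null(x$h1)) {
    cat(sprintf("  weighted planes: h1 = %g nm (Re = %g), h2 = %s\n",
                x$h1, x$re1,
                if (is.null(x$h2)) "none"
                else sprintf("%g nm (Re = %g)", x$h2, x$re2)))
  } else if (!is.null(x$slab_zmax)) {
    cat(sprintf("  acceptor slab: z ~ U[0, %g] nm\n", x$slab_zmax))
  } else {
    cat(sprintf("  acceptor plane: h = %g nm\n", x$h))
  }
  invisible(x)
}

# One Monte-Carlo pass over a single acceptor plane (or slab).
#
# Draw order per chunk: donor x, donor y, acceptor x, acceptor y,
# [slab z], donor cos(theta), donor phi, acceptor cos(theta), acceptor phi.
# Pairs closer than `re` (3D distance; also exact coincidence) have their
# position coordinates redrawn before orientations are sampled, matching the
# reference algorithm in which orientations are kept on an exclusion
# violation.
run_plane <- function(donor, acceptor, l, n, h, slab_zmax = NULL, re = 0,
                      n_bins = 100, method = "box-muller",
                      return_pairs = FALSE, chunk = 1e6) {
  edges <- seq(0, 4, length.out = n_bins + 1L)
  t_edges <- seq(0, pi, length.out = n_bins + 1L)
  counts <- numeric(n_bins)
  td_counts <- numeric(n_bins)
  ta_counts <- numeric(n_bins)
  sum_k <- 0
  sum_k2 <- 0
  sum_w <- 0
  sum_kw <- 0
  max_k <- 0
  pairs <- if (return_pairs) vector("list", ceiling(n / chunk)) else NULL
  left <- n
  ci <- 0L
  while (left > 0) {
    m <- as.integer(min(left, chunk))
    ci <- ci + 1L
    dx <- stats::runif(m, 0, l); dy <- stats::runif(m, 0, l)
    ax <- stats::runif(m, 0, l); ay <- stats::runif(m, 0, l)
    z <- if (is.null(slab_zmax)) rep(h, m) else stats::runif(m, 0, slab_zmax)
    sx <- ax - dx; sy <- ay - dy
    r2 <- sx * sx + sy * sy + z * z
    bad <- which(r2 < re * re | r2 == 0)
    iter <- 0L
    while (length(bad)) {
      iter <- iter + 1L
      if (iter > 10000L) {
        stop("geometry infeasible: exclusion distance leaves too few ",
             "admissible donor-acceptor placements", call. = FALSE)
      }
      k <- length(bad)
      dx[bad] <- stats::runif(k, 0, l); dy[bad] <- stats::runif(k, 0, l)
      ax[bad] <- stats::runif(k, 0, l); ay[bad] <- stats::runif(k, 0, l)
      sx[bad] <- ax[bad] - dx[bad]; sy[bad] <- ay[bad] - dy[bad]
      r2[bad] <- sx[bad]^2 + sy[bad]^2 + z[bad]^2
      bad <- bad[r2[bad] < re * re | r2[bad] == 0]
    }
    cd <- sample_cos_theta(donor, m, method)
    pd <- stats::runif(m, 0, 2 * pi)
    ca <- sample_cos_theta(acceptor, m, method)
    pa <- stats::runif(m, 0, 2 * pi)
    sd_ <- sqrt(pmax(0, 1 - cd * cd))
    sa_ <- sqrt(pmax(0, 1 - ca * ca))
    udx <- sd_ * cos(pd); udy <- sd_ * sin(pd)
    uax <- sa_ * cos(pa); uay <- sa_ * sin(pa)
    k2 <- kappa2_vec(udx, udy, cd, uax, uay, ca, sx, sy, z)
    k2 <- pmin(pmax(k2, 0), 4)

    counts <- counts + bin_counts(k2, edges)
    td_counts <- td_counts + bin_counts(acos(cd), t_edges)
    ta_counts <- ta_counts + bin_counts(acos(ca), t_edges)
    sum_k <- sum_k + sum(k2)
    sum_k2 <- sum_k2 + sum(k2 * k2)
    max_k <- max(max_k, max(k2))
    w <- 1 / r2^3
    sum_w <- sum_w + sum(w)
    sum_kw <- sum_kw + sum(k2 * w)
    if (return_pairs) {
      pairs[[ci]] <- data.frame(
        dx = dx, dy = dy, ax = ax, ay = ay, z = z,
        theta_d = acos(cd), phi_d = pd, theta_a = acos(ca), phi_a = pa,
        r = sqrt(r2), kappa2 = k2
      )
    }
    left <- left - m
  }
  width <- 4 / n_bins
  t_width <- pi / n_bins
  list(
    bin_edges = edges,
    density = counts / (n * width),
    theta_d_hist = data.frame(
      bin_left = t_edges[-(n_bins + 1L)], bin_right = t_edges[-1L],
      density = td_counts / (n * t_width)),
    theta_a_hist = data.frame(
      bin_left = t_edges[-(n_bins + 1L)], bin_right = t_edges[-1L],
      density = ta_counts / (n * t_width)),
    mean_unweighted = sum_k / n,
    sd_kappa2 = sqrt(max(0, sum_k2 / n - (sum_k / n)^2)),
    max_kappa2 = max_k,
    sum_w = sum_w,
    sum_kw = sum_kw,
    n_pairs = n,
    pairs = if (return_pairs) do.call(rbind, pairs) else NULL
  )
}

new_kappa2_result <- function(plane, mode, geom, seed, mean_weighted = NULL,
                              planes = NULL) {
  structure(
    list(
      mode = mode,
      bin_edges = plane$bin_edges,
      density = plane$density,
      mean_unweighted = plane$mean_unweighted,
      sd_kappa2 = plane$sd_kappa2,
      mean_weighted = mean_weighted,
      max_kappa2 = plane$max_kappa2,
      theta_d_hist = plane$theta_d_hist,
      theta_a_hist = plane$theta_a_hist,
      n_pairs = plane$n_pairs,
      seed = seed,
      geometry = geom,
      planes = planes,
      pairs = plane$pairs
    ),
    class = "kappa2_result"
  )
}

#' @export
print.kappa2_result <- function(x, ...) {
  cat(sprintf("<kappa2_result> mode = %s, %g pairs\n", x$mode, x$n_pairs))
  cat(sprintf("  mean kappa^2 (unweighted): %.4f\n", x$mean_unweighted))
  if (!is.null(x$mean_weighted)) {
    cat(sprintf("  mean kappa^2 (R^-6 weighted): %.4f\n", x$mean_weighted))
  }
  cat(sprintf("  max sampled kappa^2: %.4f\n", x$max_kappa2))
  invisible(x)
}

resolve_seed <- function(seed, geom) {
  if (is.null(seed)) seed <- geom$seed
  if (!is.null(seed)) set.seed(as.integer(seed))
  seed
}

#' Unweighted kappa-squared distribution for a single acceptor plane
#'
#' Monte-Carlo run over `n` independent donor-acceptor pairs: donor and
#' acceptor xy-positions are uniform on the `l`-by-`l` square, the donor
#' plane is `z = 0` and the acceptor plane `z = h`; orientations are drawn
#' from the two angular specifications; the orientation factor is evaluated
#' per pair.  Returns the histogram of kappa-squared over `[0, 4]`, its
#' arithmetic mean, and the tilt-angle histograms of both species.
#'
#' @param donor,acceptor [angular_spec()] objects (or `c(theta_max, sigma)`).
#' @param geom A [geometry_config()]; `h` is the interplanar distance.
#' @param seed RNG seed (overrides `geom$seed`; `NULL` uses the current
#'   stream).
#' @param method Normal generator passed to [sample_cos_theta()].
#' @param return_pairs If `TRUE`, per-pair positions, orientations and
#'   kappa-squared values are kept (memory scales with `n`; intended for
#'   small runs and cross-checks).
#' @return A `kappa2_result`: histogram (`bin_edges`, `density`),
#'   `mean_unweighted`, `max_kappa2`, tilt histograms, `n_pairs`, `seed`.
#' @examples
#' res <- simulate_unweighted(angular_spec(90, 0), angular_spec(90, 0),
#'                            geometry_config(n = 1e4, h = 0), seed = 1)
#' res$mean_unweighted  # close to 1.25
#' @export
simulate_unweighted <- function(donor, acceptor, geom = geometry_config(),
                                seed = NULL,
                                method = c("box-muller", "inversion"),
                                return_pairs = FALSE) {
  donor <- as_angular_spec(donor)
  acceptor <- as_angular_spec(acceptor)
  stopifnot(inherits(geom, "geometry_config"))
  method <- match.arg(method)
  seed <- resolve_seed(seed, geom)
  plane <- run_plane(donor, acceptor, geom$l, geom$n, geom$h,
                     re = 0, n_bins = geom$n_bins, method = method,
                     return_pairs = return_pairs)
  new_kappa2_result(plane, "unweighted", geom, seed)
}

#' Unweighted run with acceptors in a 3D slab
#'
#' Identical to [simulate_unweighted()] except that the acceptor `z`
#' coordinate of each pair is uniform on `[0, slab_zmax]`, emulating
#' acceptors distributed through a slab rather than a single plane.  With
#' near-isotropic orientations this reproduces the three-dimensional
#' isotropic average of 2/3.
#'
#' @inheritParams simulate_unweighted
#' @param geom A [geometry_config()] with `slab_zmax` set.
#' @return A `kappa2_result`.
#' @export
simulate_unweighted_slab <- function(donor, acceptor, geom, seed = NULL,
                                     method = c("box-muller", "inversion"),
                                     return_pairs = FALSE) {
  donor <- as_angular_spec(donor)
  acceptor <- as_angular_spec(acceptor)
  stopifnot(inherits(geom, "geometry_config"))
  if (is.null(geom$slab_zmax)) {
    stop("`geom$slab_zmax` must be set for a slab run", call. = FALSE)
  }
  method <- match.arg(method)
  seed <- resolve_seed(seed, geom)
  plane <- run_plane(donor, acceptor, geom$l, geom$n, h = 0,
                     slab_zmax = geom$slab_zmax, re = 0,
                     n_bins = geom$n_bins, method = method,
                     return_pairs = return_pairs)
  new_kappa2_result(plane, "slab", geom, seed)
}

#' Distance-weighted kappa-squared average over one or two acceptor planes
#'
#' Replicates the bilayer averaging scheme: because the FRET rate from a
#' donor to acceptor `i` scales as `kappa_i^2 / R_i^6`, the natural average
#' over acceptors at varying distances weights each pair by the inverse
#' sixth power of its separation,
#' \deqn{\langle\kappa^2\rangle = \sum_i \kappa_i^2 R_i^{-6} / \sum_i R_i^{-6}.}
#' One cycle of `n` pairs is run for the acceptor plane at `h1` and (if
#' `h2` is set) a second cycle for the plane at `h2` — the two bilayer
#' leaflets, at equal acceptor surface density.  Pairs closer than the
#' plane's exclusion distance are re-placed (positions only).  Partial sums
#' are pooled across cycles for the weighted mean; per-plane unweighted
#' histograms and means are also returned.
#'
#' @inheritParams simulate_unweighted
#' @param geom A [geometry_config()] with `h1` (and optionally `h2`) set;
#'   a plane with `h = 0` must have a positive exclusion distance.
#' @return A `kappa2_result` with `mean_weighted` (pooled) and a `planes`
#'   list holding each cycle's histogram and unweighted mean.  The top-level
#'   histogram pools both cycles' (unweighted) kappa-squared samples.
#' @examples
#' g <- geometry_config(n = 1e4, h1 = 0, h2 = 2, re1 = 0.8, re2 = 0.8)
#' simulate_weighted(angular_spec(90, 0), angular_spec(90, 0), g, seed = 1)
#' @export
simulate_weighted <- function(donor, acceptor, geom, seed = NULL,
                              method = c("box-muller", "inversion"),
                              return_pairs = FALSE) {
  donor <- as_angular_spec(donor)
  acceptor <- as_angular_spec(acceptor)
  stopifnot(inherits(geom, "geometry_config"))
  if (is.null(geom$h1)) {
    stop("`geom$h1` must be set for a weighted run", call. = FALSE)
  }
  if (geom$h1 == 0 && geom$re1 <= 0) {
    stop("a coplanar weighted plane (h1 = 0) requires `re1` > 0",
         call. = FALSE)
  }
  if (!is.null(geom$h2) && geom$h2 == 0 && geom$re2 <= 0) {
    stop("a coplanar weighted plane (h2 = 0) requires `re2` > 0",
         call. = FALSE)
  }
  method <- match.arg(method)
  seed <- resolve_seed(seed, geom)

  p1 <- run_plane(donor, acceptor, geom$l, geom$n, geom$h1, re = geom$re1,
                  n_bins = geom$n_bins, method = method,
                  return_pairs = return_pairs)
  planes <- list(plane1 = p1)
  if (!is.null(geom$h2)) {
    p2 <- run_plane(donor, acceptor, geom$l, geom$n, geom$h2, re = geom$re2,
                    n_bins = geom$n_bins, method = method,
                    return_pairs = return_pairs)
    planes$plane2 <- p2
    pooled <- list(
      bin_edges = p1$bin_edges,
      density = (p1$density + p2$density) / 2,
      theta_d_hist = within(p1$theta_d_hist,
                            density <- (density + p2$theta_d_hist$density) / 2),
      theta_a_hist = within(p1$theta_a_hist,
                            density <- (density + p2$theta_a_hist$density) / 2),
      mean_unweighted = (p1$mean_unweighted + p2$mean_unweighted) / 2,
      sd_kappa2 = {
        msq <- (p1$sd_kappa2^2 + p1$mean_unweighted^2 +
                  p2$sd_kappa2^2 + p2$mean_unweighted^2) / 2
        sqrt(max(0, msq - ((p1$mean_unweighted + p2$mean_unweighted) / 2)^2))
      },
      max_kappa2 = max(p1$max_kappa2, p2$max_kappa2),
      n_pairs = p1$n_pairs + p2$n_pairs,
      pairs = if (return_pairs) rbind(p1$pairs, p2$pairs) else NULL
    )
  } else {
    pooled <- p1
  }
  mean_w <- (p1$sum_kw + if (is.null(geom$h2)) 0 else p2$sum_kw) /
    (p1$sum_w + if (is.null(geom$h2)) 0 else p2$sum_w)
  planes <- lapply(planes, function(p) {
    p[c("bin_edges", "density", "mean_unweighted", "sd_kappa2",
        "max_kappa2", "sum_w", "sum_kw", "n_pairs")]
  })
  new_kappa2_result(pooled, "weighted", geom, seed,
                    mean_weighted = mean_w, planes = planes)
}

#' Repeat a simulation over independent seeds
#'
#' Runs a simulation `n_repeats` times with distinct seeds and summarizes
#' the run means, mirroring the convergence check of repeating each Monte
#' Carlo estimate ten times and reporting mean and standard deviation.
#'
#' @param fun A simulation function accepting a `seed` argument and
#'   returning a `kappa2_result` ([simulate_unweighted()],
#'   [simulate_weighted()], ...), or any function returning an object with
#'   `mean_weighted`/`mean_unweighted` fields.
#' @param ... Arguments passed on to `fun` (specs, geometry, ...).
#' @param n_repeats Number of repeats (`>= 2`).
#' @param base_seed First seed; repeats use `base_seed + 0:(n_repeats-1)`.
#' @param seeds Optional explicit seed vector overriding `base_seed`.
#' @return An object of class `repeat_summary`: `means`, `grand_mean`,
#'   `std_dev`, `n_repeats`, `seeds`.
#' @examples
#' g <- geometry_config(n = 1e4, h = 0)
#' repeat_runs(simulate_unweighted, angular_spec(90, 3), angular_spec(90, 3),
#'             g, n_repeats = 3, base_seed = 1)
#' @export
repeat_runs <- function(fun, ..., n_repeats = 10, base_seed = 1,
                        seeds = NULL) {
  if (is.null(seeds)) {
    n_repeats <- as.integer(n_repeats)
    if (is.na(n_repeats) || n_repeats < 2L) {
      stop("`n_repeats` must be at least 2", call. = FALSE)
    }
    seeds <- as.integer(base_seed) + seq_len(n_repeats) - 1L
  }
  means <- vapply(seeds, function(s) {
    res <- fun(..., seed = s)
    if (!is.null(res$mean_weighted)) res$mean_weighted else res$mean_unweighted
  }, numeric(1))
  structure(
    list(means = means, grand_mean = mean(means),
         std_dev = stats::sd(means), n_repeats = length(seeds),
         seeds = seeds),
    class = "repeat_summary"
  )
}

#' @export
print.repeat_summary <- function(x, ...) {
  cat(sprintf("<repeat_summary> %d runs: <kappa^2> = %.4f (sd %.4f)\n",
              x$n_repeats, x$grand_mean, x$std_dev))
  invisible(x)
}
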