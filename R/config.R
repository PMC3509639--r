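config_defaults <- function() {
  list(
    mode = "unweighted",
    theta_d_max_deg = 90, sigma_d = 0,
    theta_a_max_deg = 90, sigma_a = 0,
    l = 100, n = 1e6, h = 0,
    h1 = NULL, h2 = NULL, re1 = 0.8, re2 = 0.8,
    slab_zmax = NULL, n_bins = 100, seed = NULL,
    repeats = 1, normal_method = "box-muller"
  )
}

#' Read a run configuration from a YAML file
#'
#' Keys mirror the simulator arguments: `mode`
#' (`unweighted`/`slab`/`weighted`), `theta_d_max_deg`, `sigma_d`,
#' `theta_a_max_deg`, `sigma_a`, `l`, `n`, `h`, `h1`, `h2`, `re1`, `re2`,
#' `slab_zmax`, `n_bins`, `seed`, `repeats`, `normal_method`.  Angles are
#' degrees, distances nm.  Missing keys take the package defaults
#' (`l = 100`, `n = 1e6`, `n_bins = 100`, `Re = 0.8` where weighting is
#' requested); unknown keys and out-of-range values raise descriptive
#' errors.
#'
#' @param path Path to a YAML file (an empty file yields all defaults).
#' @return A validated configuration list of class `kappa2_config` with
#'   elements `donor`, `acceptor` ([angular_spec()]), `geom`
#'   ([geometry_config()]), `mode`, `repeats`, `normal_method`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("config file not found: %s", path), call. = FALSE)
  }
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  defs <- config_defaults()
  unknown <- setdiff(names(raw), names(defs))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg <- utils::modifyList(defs, raw, keep.null = TRUE)
  if (!cfg$mode %in% c("unweighted", "slab", "weighted")) {
    stop("`mode` must be one of unweighted, slab, weighted", call. = FALSE)
  }
  if (!cfg$normal_method %in% c("box-muller", "inversion")) {
    stop("`normal_method` must be box-muller or inversion", call. = FALSE)
  }
  chk <- function(key, lo, hi = Inf) {
    v <- cfg[[key]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < lo || v > hi) {
      stop(sprintf("config key `%s` must be a number in [%g, %g]",
                   key, lo, hi), call. = FALSE)
    }
  }
  chk("theta_d_max_deg", 0, 180)
  chk("theta_a_max_deg", 0, 180)
  chk("sigma_d", 0)
  chk("sigma_a", 0)
  chk("repeats", 1)
  donor <- angular_spec(cfg$theta_d_max_deg, cfg$sigma_d)
  acceptor <- angular_spec(cfg$theta_a_max_deg, cfg$sigma_a)
  if (cfg$mode == "weighted" && is.null(cfg$h1)) cfg$h1 <- 0
  geom <- geometry_config(l = cfg$l, n = cfg$n, h = cfg$h, h1 = cfg$h1,
                          h2 = cfg$h2, re1 = cfg$re1, re2 = cfg$re2,
                          slab_zmax = cfg$slab_zmax, n_bins = cfg$n_bins,
                          seed = cfg$seed)
  structure(
    list(mode = cfg$mode, donor = donor, acceptor = acceptor, geom = geom,
         repeats = cfg$repeats, normal_method = cfg$normal_method),
    class = "kappa2_config"
  )
}

#' Write simulation results to disk
#'
#' Writes the kappa-squared histogram as CSV (`bin_left`, `bin_right`,
#' `density`), the tilt histograms as CSV, a JSON summary (means, maximum,
#' pair count, seed, geometry echo) and a manifest JSON listing every file
#' written.  Output is deterministic for a fixed seed.
#'
#' @param result A `kappa2_result`.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Invisibly, a named character vector of the written paths.
#' @export
write_results <- function(result, dir, prefix = "kappa2") {
  stopifnot(inherits(result, "kappa2_result"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  nb <- length(result$density)
  hist_df <- data.frame(
    bin_left = result$bin_edges[-(nb + 1L)],
    bin_right = result$bin_edges[-1L],
    density = result$density
  )
  paths <- c(
    histogram = file.path(dir, paste0(prefix, "_histogram.csv")),
    theta_d = file.path(dir, paste0(prefix, "_theta_d.csv")),
    theta_a = file.path(dir, paste0(prefix, "_theta_a.csv")),
    summary = file.path(dir, paste0(prefix, "_summary.json")),
    manifest = file.path(dir, paste0(prefix, "_manifest.json"))
  )
  utils::write.csv(hist_df, paths[["histogram"]], row.names = FALSE)
  utils::write.csv(result$theta_d_hist, paths[["theta_d"]],
                   row.names = FALSE)
  utils::write.csv(result$theta_a_hist, paths[["theta_a"]],
                   row.names = FALSE)
  geom <- result$geometry
  summary <- list(
    mode = result$mode,
    mean_unweighted = result$mean_unweighted,
    mean_weighted = result$mean_weighted,
    max_kappa2 = result$max_kappa2,
    n_pairs = result$n_pairs,
    seed = result$seed,
    geometry = geom[!vapply(geom, is.null, logical(1))]
  )
  jsonlite::write_json(summary, paths[["summary"]], auto_unbox = TRUE,
                       digits = NA, null = "null")
  manifest <- list(
    package = "kappa2sim",
    version = as.character(utils::packageVersion("kappa2sim")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = result$seed,
    files = as.list(paths[setdiff(names(paths), "manifest")])
  )
  jsonlite::write_json(manifest, paths[["manifest"]], auto_unbox = TRUE,
                       null = "null")
  invisible(paths)
}

#' Read a histogram CSV written by [write_results()]
#'
#' @param path Path to a `*_histogram.csv` file.
#' @return A data frame with columns `bin_left`, `bin_right`, `density`.
#' @export
read_histogram <- function(path) {
  utils::read.csv(path)
}
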