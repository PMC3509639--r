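#' Catalogue of common membrane FRET probe pairs
#'
#' Literature-derived transverse locations (distance of the fluorophore
#' plane from the bilayer centre, nm) and orientation parameters
#' `(theta_max, sigma)` for membrane probes commonly used as FRET donors
#' and acceptors: trans-parinaric acid (t-PnA), diphenylhexatriene (DPH),
#' NBD, a carbocyanine, Rhodamine B and BODIPY.  Each pair defines a
#' bilayer geometry with the donor plane at `z = 0` and acceptor planes at
#' `h1 = |z_D - z_A|` (same leaflet) and `h2 = z_D + z_A` (opposite
#' leaflet).  The `tPnA_DPH_gel` entry replaces only the t-PnA donor
#' orientation by its gel-phase values (5 degrees, 0.03), keeping the
#' fluid-phase locations and the DPH acceptor parameters.
#'
#' @return A data frame with one row per preset: `name`, `donor`,
#'   `acceptor`, `donor_z`, `acceptor_z`, `donor_theta_max`, `donor_sigma`,
#'   `acceptor_theta_max`, `acceptor_sigma`, `h1`, `h2` (all distances nm,
#'   angles degrees).
#' @examples
#' preset_catalogue()
#' @export
preset_catalogue <- function() {
  # fluorophore parameters, each printed once in the source literature:
  # t-PnA 0.92 nm (20, 0.15); DPH 0.75 nm (0, 0.35); NBD 1.35 nm (125, 0.35);
  # carbocyanine 1.26 nm (77, 0.25); Rhodamine B 2.1 nm (90, 0.275);
  # BODIPY 0.8 nm (10, 0.5); gel-phase t-PnA (5, 0.03).
  row <- function(name, d, a, dz, dth, dsg, az, ath, asg) {
    data.frame(name = name, donor = d, acceptor = a,
               donor_z = dz, acceptor_z = az,
               donor_theta_max = dth, donor_sigma = dsg,
               acceptor_theta_max = ath, acceptor_sigma = asg)
  }
  cat <- rbind(
    row("tPnA_DPH",          "t-PnA",      "DPH",          0.92, 20, 0.15, 0.75,  0, 0.35),
    row("DPH_NBD",           "DPH",        "NBD",          0.75,  0, 0.35, 1.35, 125, 0.35),
    row("NBD_NBD",           "NBD",        "NBD",          1.35, 125, 0.35, 1.35, 125, 0.35),
    row("NBD_carbocyanine",  "NBD",        "carbocyanine", 1.35, 125, 0.35, 1.26, 77, 0.25),
    row("NBD_rhodamineB",    "NBD",        "Rhodamine B",  1.35, 125, 0.35, 2.10, 90, 0.275),
    row("BODIPY_rhodamineB", "BODIPY",     "Rhodamine B",  0.80, 10, 0.50, 2.10, 90, 0.275),
    row("BODIPY_carbocyanine", "BODIPY",   "carbocyanine", 0.80, 10, 0.50, 1.26, 77, 0.25),
    row("rhodamineB_homo",   "Rhodamine B", "Rhodamine B", 2.10, 90, 0.275, 2.10, 90, 0.275),
    row("tPnA_DPH_gel",      "t-PnA (gel)", "DPH",         0.92,  5, 0.03, 0.75,  0, 0.35)
  )
  cat$h1 <- abs(cat$donor_z - cat$acceptor_z)
  cat$h2 <- cat$donor_z + cat$acceptor_z
  cat
}

#' Run a probe-pair preset through the weighted bilayer simulator
#'
#' Looks up a preset from [preset_catalogue()], builds the two-plane
#' geometry (`h1 = |z_D - z_A|`, `h2 = z_D + z_A`, exclusion `re` on both
#' planes) and repeats the distance-weighted simulation over independent
#' seeds.  The defaults reproduce the catalogue run conditions: ten
#' repeats of 10^6 pairs per plane with `Re = 0.8` nm and `l = 100` nm.
#'
#' @param name Preset name (see [preset_catalogue()]).
#' @param n Pairs per plane and repeat.
#' @param n_repeats Number of independent repeats.
#' @param base_seed First seed.
#' @param l Square side, nm.
#' @param re Exclusion distance for both planes, nm.
#' @param n_bins Histogram bins.
#' @param out_dir Optional directory; when set, the first repeat's full
#'   result is written there via [write_results()].
#' @return A `repeat_summary` (see [repeat_runs()]) with the preset row
#'   attached as attribute `"preset"`.
#' @examples
#' run_preset("rhodamineB_homo", n = 1e4, n_repeats = 2, base_seed = 1)
#' @export
run_preset <- function(name, n = 1e6, n_repeats = 10, base_seed = 1,
                       l = 100, re = 0.8, n_bins = 100, out_dir = NULL) {
  cat <- preset_catalogue()
  i <- match(name, cat$name)
  if (is.na(i)) {
    stop(sprintf("unknown preset '%s'; see preset_catalogue()$name", name),
         call. = FALSE)
  }
  p <- cat[i, ]
  donor <- angular_spec(p$donor_theta_max, p$donor_sigma)
  acceptor <- angular_spec(p$acceptor_theta_max, p$acceptor_sigma)
  geom <- geometry_config(l = l, n = n, h1 = p$h1, h2 = p$h2,
                          re1 = re, re2 = re, n_bins = n_bins)
  summ <- repeat_runs(simulate_weighted, donor, acceptor, geom,
                      n_repeats = n_repeats, base_seed = base_seed)
  if (!is.null(out_dir)) {
    res <- simulate_weighted(donor, acceptor, geom,
                             seed = as.integer(base_seed))
    write_results(res, out_dir, prefix = name)
  }
  attr(summ, "preset") <- p
  summ
}
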