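#' Default incubation-condition parameters for the synthetic study
#'
#' Per-condition generator settings emulating the published per-time-point
#' statistics of SPION-containing vesicles in MCF-7 cells: mean vesicle
#' counts per cell rising from ~85 (3 h) to ~170 (24 h), mean equivalent
#' diameters rising from ~320 nm (control) to ~570 nm (12 h), diameter SDs of
#' 87-70 nm between 3 and 12 h (96 nm at 24 h, 39 nm in controls), and
#' centre-separation floors of 412/408/325/325/340 nm. The perinuclear shell
#' (2.3-3.8 um from the nuclear surface) and the 100-1000 nm diameter
#' truncation are shared by all conditions. The control mean count (30) and
#' the 3/6/24 h mean diameters are package choices consistent with the
#' published count, diameter and accumulated-volume anchors; see the methods
#' vignette.
#'
#' @return data frame, one row per condition.
#' @export
#' @examples
#' scv_conditions()
scv_conditions <- function() {
  data.frame(
    condition = c("CTR", "3h", "6h", "12h", "24h"),
    time_h = c(0, 3, 6, 12, 24),
    n_mean = c(30, 85, 110, 160, 170),
    diameter_mean_nm = c(320, 525, 545, 570, 590),
    diameter_sd_nm = c(39, 87, 75, 70, 96),
    min_separation_nm = c(412, 408, 325, 325, 340),
    shell_min_nm = 2300,
    shell_max_nm = 3800,
    stringsAsFactors = FALSE
  )
}

#' Published tilt-series acquisition plan
#'
#' The per-condition tilt-series counts of the study this package emulates:
#' 69 series at the ALBA Mistral beamline (21 at 3 h, 13 at 6 h, 20 at 12 h,
#' 7 at 24 h, 8 controls; 11.5 nm pixel) and 24 series at HZB-BESSYII
#' (24 h; 15.56 nm pixel), all acquired from -70 to 70 degrees at 1 degree
#' intervals. Shipped as `inst/extdata/acquisition_plan.csv`.
#'
#' @return data frame with columns `facility, condition, incubation_h,
#'   n_tilt_series, pixel_size_nm`.
#' @export
#' @examples
#' plan <- acquisition_plan()
#' sum(plan$n_tilt_series[plan$facility == "ALBA"])
acquisition_plan <- function() {
  utils::read.csv(system.file("extdata", "acquisition_plan.csv",
                              package = "scvtomo", mustWork = TRUE),
                  stringsAsFactors = FALSE)
}

#' Generate a complete synthetic cell for one condition
#'
#' Draws the vesicle count (Poisson around `n_mean`, capped at
#' `n_mean + 3 sqrt(n_mean)` to stay inside the packing regime the placer
#' supports), samples diameters from the condition's truncated lognormal,
#' and places the vesicles in the perinuclear shell.
#'
#' @param condition one row of [scv_conditions()] (or a list with the same
#'   fields).
#' @param extent_nm length-3 cytoplasm extent (nm).
#' @param nucleus a [nucleus_model()]; by default an ellipsoid with semi-axes
#'   2.2/1.8/1.1 um centred in the extent.
#' @param background_lac,nucleus_lac,contrast_ratio LAC model (1/um);
#'   vesicle LAC is `contrast_ratio * background_lac`.
#' @param seed integer seed; the count, diameters and placement each use a
#'   seed derived from it via [derive_seed()].
#' @return a [cell_phantom()].
#' @export
generate_cell_phantom <- function(condition, extent_nm,
                                  nucleus = NULL,
                                  background_lac = 0.30, nucleus_lac = 0.40,
                                  contrast_ratio = 3, seed = 1) {
  condition <- as.list(condition)
  if (is.null(nucleus))
    nucleus <- nucleus_model(centre_nm = extent_nm / 2,
                             semi_axes_nm = c(2200, 1800, 1100),
                             lac = nucleus_lac)
  n <- run_seeded(derive_seed(seed, 1), function()
    stats::rpois(1L, condition$n_mean))
  n <- min(n, as.integer(round(condition$n_mean + 3 * sqrt(condition$n_mean))))
  spec <- placement_spec(
    n_vesicles = n,
    shell_nm = c(condition$shell_min_nm, condition$shell_max_nm),
    min_separation_nm = condition$min_separation_nm,
    diameter_mean_nm = condition$diameter_mean_nm,
    diameter_sd_nm = condition$diameter_sd_nm
  )
  diam <- sample_vesicle_diameters(n, condition$diameter_mean_nm,
                                   condition$diameter_sd_nm,
                                   spec$diameter_bounds_nm,
                                   seed = derive_seed(seed, 2))
  centres <- place_vesicles(nucleus, spec, diam, extent_nm,
                            seed = derive_seed(seed, 3))
  ves <- data.frame(x_nm = centres[, 1], y_nm = centres[, 2],
                    z_nm = centres[, 3], diameter_nm = diam)
  cell_phantom(nucleus, ves, background_lac = background_lac,
               extent_nm = extent_nm, contrast_ratio = contrast_ratio,
               seed = seed)
}
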