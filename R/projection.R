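#' Single-axis tilt geometry
#'
#' Inclusive arithmetic sequence of tilt angles about one grid axis, plus the
#' detector pixel size. The default range, -70 to 70 degrees at 1 degree
#' intervals, is the standard limited-tilt acquisition for cryo-soft X-ray
#' tomography of plunge-frozen grids; angles beyond +/-70 degrees form the
#' missing wedge.
#'
#' @param start_deg,stop_deg first and last angle (degrees), both in
#'   `[-90, 90]`, `start_deg <= stop_deg`.
#' @param step_deg positive angular increment (degrees).
#' @param pixel_size_nm detector pixel size (nm); equals the reconstruction
#'   voxel size.
#' @param rotation_axis grid axis the stage rotates about; only `"y"` (the
#'   second array dimension) is supported.
#' @return object of class `tilt_geometry`.
#' @export
#' @examples
#' g <- make_tilt_geometry(-70, 70, 1, pixel_size_nm = 11.5)
#' length(g$angles_deg)  # 141
make_tilt_geometry <- function(start_deg = -70, stop_deg = 70, step_deg = 1,
                               pixel_size_nm, rotation_axis = "y") {
  if (!is.numeric(step_deg) || step_deg <= 0)
    stop("'step_deg' must be > 0")
  if (start_deg > stop_deg) stop("'start_deg' must be <= 'stop_deg'")
  if (start_deg < -90 || stop_deg > 90)
    stop("tilt angles must lie in [-90, 90] degrees")
  if (!identical(rotation_axis, "y"))
    stop("only rotation about the y axis is supported")
  if (pixel_size_nm <= 0) stop("'pixel_size_nm' must be > 0")
  angles <- seq(start_deg, stop_deg, by = step_deg)
  structure(list(angles_deg = angles, rotation_axis = "y",
                 pixel_size_nm = pixel_size_nm),
            class = "tilt_geometry")
}

#' @export
print.tilt_geometry <- function(x, ...) {
  cat(sprintf("<tilt_geometry> %d angles, %.4g to %.4g deg, pixel %.4g nm\n",
              length(x$angles_deg), min(x$angles_deg), max(x$angles_deg),
              x$pixel_size_nm))
  invisible(x)
}

default_ndet <- function(nx, nz) as.integer(ceiling(sqrt(nx^2 + nz^2))) + 1L

#' Line-integral forward projection
#'
#' Applies the parallel-beam projector to a volume: for every tilt angle and
#' detector pixel, the integral of the LAC along the ray, in units of
#' absorbance (LAC in 1/um times path length in um). This is the noiseless
#' ideal measurement; [project_tilt_series()] adds the Beer-Lambert intensity
#' model and photon noise on top of it.
#'
#' @param volume an [sxt_volume()] (LAC in 1/um).
#' @param geometry a [make_tilt_geometry()]; its pixel size must match the
#'   volume voxel size.
#' @param n_det number of detector pixels per projection row; defaults to
#'   covering the volume diagonal.
#' @return array `(n_det, ny, n_angles)` of absorbance line integrals.
#' @export
forward_project <- function(volume, geometry, n_det = NULL) {
  stopifnot(inherits(volume, "sxt_volume"), inherits(geometry, "tilt_geometry"))
  if (abs(geometry$pixel_size_nm - volume$voxel_size_nm) >
      1e-6 * volume$voxel_size_nm)
    stop(sprintf("detector pixel (%.4g nm) must match the voxel size (%.4g nm)",
                 geometry$pixel_size_nm, volume$voxel_size_nm))
  d <- dim(volume$values)
  if (is.null(n_det)) n_det <- default_ndet(d[1], d[3])
  sino <- cpp_forward_project(volume$values, d,
                              geometry$angles_deg * pi / 180,
                              as.integer(n_det), 1.0)
  sino * (volume$voxel_size_nm / 1000)
}

#' Backprojection (adjoint of the forward projector)
#'
#' Exact adjoint of [forward_project()] with the same sampling weights;
#' used by the SIRT solver and exposed for operator diagnostics.
#'
#' @param sino array `(n_det, ny, n_angles)`.
#' @param geometry a [make_tilt_geometry()].
#' @param dim length-3 volume dimensions.
#' @param voxel_size_nm voxel size of the target grid (nm).
#' @return numeric 3D array.
#' @export
back_project <- function(sino, geometry, dim, voxel_size_nm) {
  stopifnot(length(base::dim(sino)) == 3L)
  vol <- cpp_back_project(sino, base::dim(sino), as.integer(dim),
                          geometry$angles_deg * pi / 180, 1.0)
  vol * (voxel_size_nm / 1000)
}

#' Simulate a recorded tilt series (Beer-Lambert + Poisson noise)
#'
#' For each ray the noiseless expected intensity is
#' `I = I0 * exp(-integral mu dl)`. With a finite `photon_budget` the
#' incident intensity is `I0 = photon_budget` expected counts per pixel and
#' recorded counts are Poisson-distributed around the expectation; with
#' `photon_budget = Inf` the recorded intensity equals the expectation with
#' `I0 = 1`. The flatfield reference is stored noise-free (a separately
#' averaged beam image).
#'
#' @param volume an [sxt_volume()] of non-negative LAC values.
#' @param geometry a [make_tilt_geometry()].
#' @param photon_budget expected incident counts per pixel; `Inf` for the
#'   noiseless ideal.
#' @param seed optional integer seed for the photon noise.
#' @param n_det detector pixels per row (default: volume diagonal).
#' @return object of class `tilt_series` with elements `projections`
#'   (`n_det x ny x n_angles` recorded intensities), `geometry`, `flatfield`
#'   (`n_det x ny`), and `photon_budget`.
#' @export
project_tilt_series <- function(volume, geometry, photon_budget = Inf,
                                seed = NULL, n_det = NULL) {
  if (min(volume$values) < 0)
    stop("LAC volume must be non-negative everywhere")
  absorb <- forward_project(volume, geometry, n_det)
  i0 <- if (is.finite(photon_budget)) photon_budget else 1
  if (is.finite(photon_budget) && photon_budget <= 0)
    stop("'photon_budget' must be positive")
  expected <- i0 * exp(-absorb)
  proj <- if (is.finite(photon_budget)) {
    run_seeded(seed, function() {
      array(stats::rpois(length(expected), expected), base::dim(expected))
    })
  } else expected
  structure(list(projections = proj, geometry = geometry,
                 flatfield = matrix(i0, base::dim(proj)[1], base::dim(proj)[2]),
                 photon_budget = photon_budget),
            class = "tilt_series")
}

#' @export
print.tilt_series <- function(x, ...) {
  d <- base::dim(x$projections)
  cat(sprintf("<tilt_series> %d projections of %d x %d px, budget %s counts/px\n",
              d[3], d[1], d[2],
              if (is.finite(x$photon_budget)) format(x$photon_budget) else "Inf"))
  invisible(x)
}

#' Flatfield normalization to absorbance
#'
#' Converts recorded intensities to absorbance, `A = -log(I / I0)`, using the
#' stored flatfield reference. Non-positive recorded intensities have no
#' defined absorbance and raise an error naming the first offending pixel;
#' for photon-starved data a small positive `min_counts` floor may be applied
#' first (and is recorded by the pipeline log when used).
#'
#' @param series a [project_tilt_series()] result.
#' @param min_counts optional positive floor applied to recorded counts
#'   before taking the log.
#' @return array `(n_det, ny, n_angles)` of absorbances.
#' @export
normalize_flatfield <- function(series, min_counts = NULL) {
  stopifnot(inherits(series, "tilt_series"))
  i0 <- series$flatfield
  if (any(i0 <= 0)) stop("flatfield must be positive everywhere")
  proj <- series$projections
  if (!is.null(min_counts)) {
    if (min_counts <= 0) stop("'min_counts' must be positive")
    proj <- pmax(proj, min_counts)
  }
  if (min(proj) <= 0) {
    bad <- which(proj <= 0, arr.ind = TRUE)[1L, ]
    stop(sprintf(
      "non-positive recorded intensity at pixel (%d, %d) of projection %d; %s",
      bad[1], bad[2], bad[3],
      "cannot take the log (consider a 'min_counts' floor for noisy data)"))
  }
  absorb <- array(0, base::dim(proj))
  for (a in seq_len(base::dim(proj)[3]))
    absorb[, , a] <- -log(proj[, , a] / i0)
  absorb
}
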