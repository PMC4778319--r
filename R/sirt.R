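#' SIRT reconstruction of an absorbance tilt series
#'
#' Simultaneous iterative reconstruction technique with row/column-sum
#' (SART-family) weighting: starting from a zero volume,
#' `x <- x + relaxation * C (A' R (b - A x))`, where `R` and `C` are the
#' reciprocal row and column sums of the projection operator `A`. The
#' default of 30 iterations is the standard operating point for
#' limited-tilt cryo-soft X-ray data. The input is absorbance
#' (`-log(I/I0)`, see [normalize_flatfield()]), so the reconstruction is a
#' linear absorption coefficient map in 1/um on the projection grid's voxel
#' size.
#'
#' The projection-space residual norm `||A x_k - b||` before each update is
#' recorded in the `"sirt_residuals"` attribute of the returned volume; for
#' noiseless consistent data it is non-increasing.
#'
#' @param absorbance array `(n_det, ny, n_angles)` of absorbances.
#' @param geometry a [make_tilt_geometry()]; `pixel_size_nm` sets the voxel
#'   size of the reconstruction.
#' @param dim length-3 target grid `(nx, ny, nz)`; `ny` must match the stack.
#' @param iterations number of SIRT iterations (>= 1).
#' @param relaxation relaxation factor of the update (default 1).
#' @return an [sxt_volume()] with attribute `"sirt_residuals"` (numeric
#'   vector of length `iterations`).
#' @export
#' @seealso [sirt_residuals()]
reconstruct_sirt <- function(absorbance, geometry, dim, iterations = 30,
                             relaxation = 1.0) {
  if (iterations < 1) stop("'iterations' must be >= 1")
  if (!all(is.finite(absorbance))) stop("absorbance stack must be finite")
  sdim <- base::dim(absorbance)
  if (length(sdim) != 3L)
    stop("'absorbance' must be an (n_det, ny, n_angles) array")
  dim <- as.integer(dim)
  if (length(dim) != 3L) stop("'dim' must have length 3")
  if (sdim[2] != dim[2])
    stop(sprintf("slice count mismatch: stack has ny = %d, grid ny = %d",
                 sdim[2], dim[2]))
  if (sdim[3] != length(geometry$angles_deg))
    stop(sprintf("angle count mismatch: stack has %d projections, geometry %d angles",
                 sdim[3], length(geometry$angles_deg)))
  vox <- geometry$pixel_size_nm
  ang <- geometry$angles_deg * pi / 180
  scale <- vox / 1000  # voxel-unit line integrals -> absorbance for LAC in 1/um
  fp <- function(x) cpp_forward_project(x, dim, ang, sdim[1], 1.0) * scale
  bp <- function(b) cpp_back_project(b, sdim, dim, ang, 1.0) * scale

  row_sum <- fp(array(1, dim))
  col_sum <- bp(array(1, sdim))
  rw <- ifelse(row_sum > 1e-9, 1 / pmax(row_sum, 1e-9), 0)
  cw <- ifelse(col_sum > 1e-9, 1 / pmax(col_sum, 1e-9), 0)

  x <- array(0, dim)
  residuals <- numeric(iterations)
  for (k in seq_len(iterations)) {
    r <- absorbance - fp(x)
    residuals[k] <- sqrt(sum(r^2))
    x <- x + relaxation * cw * bp(rw * r)
  }
  out <- sxt_volume(x, vox)
  attr(out, "sirt_residuals") <- residuals
  out
}

#' Residual history of a SIRT reconstruction
#'
#' @param volume a volume returned by [reconstruct_sirt()].
#' @return numeric vector of projection-space residual norms, one per
#'   iteration (measured before each update).
#' @export
sirt_residuals <- function(volume) {
  r <- attr(volume, "sirt_residuals")
  if (is.null(r)) stop("volume carries no SIRT residual history")
  r
}
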