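#' Segmentation parameters
#'
#' @param threshold_mode `"otsu_top_decile"` (default; Otsu's between-class
#'   criterion restricted to voxels above the 90th intensity percentile,
#'   operationalizing a threshold "adapted to the highest densities"),
#'   `"otsu"` (whole volume), `"percentile"` (fixed upper quantile), or
#'   `"fixed"` (explicit `threshold` value).
#' @param min_diameter_nm components with equivalent diameter below this are
#'   discarded (default 100 nm, the practical detection floor).
#' @param connectivity 26 (full 3D neighbourhood, default: diagonally
#'   touching voxels merge, matching the compact appearance of vesicle
#'   clusters) or 6.
#' @param percentile upper-tail fraction defining the candidate voxels for
#'   `"otsu_top_decile"` (default 0.90) or the threshold quantile for
#'   `"percentile"` mode (default 0.99).
#' @param threshold explicit LAC threshold for `"fixed"` mode.
#' @return object of class `segmentation_params`.
#' @export
segmentation_params <- function(threshold_mode = c("otsu_top_decile", "otsu",
                                                   "percentile", "fixed"),
                                min_diameter_nm = 100,
                                connectivity = 26,
                                percentile = NULL,
                                threshold = NULL) {
  threshold_mode <- match.arg(threshold_mode)
  if (min_diameter_nm < 0) stop("'min_diameter_nm' must be >= 0")
  if (!connectivity %in% c(6, 26)) stop("'connectivity' must be 6 or 26")
  if (threshold_mode == "fixed" && is.null(threshold))
    stop("'fixed' mode requires a 'threshold'")
  if (is.null(percentile))
    percentile <- if (threshold_mode == "percentile") 0.99 else 0.90
  structure(list(threshold_mode = threshold_mode,
                 min_diameter_nm = min_diameter_nm,
                 connectivity = as.integer(connectivity),
                 percentile = percentile, threshold = threshold),
            class = "segmentation_params")
}

# standard 256-bin Otsu on a numeric vector: maximize between-class variance
otsu_threshold <- function(values, levels = 256L) {
  rng <- range(values)
  if (diff(rng) == 0) stop("cannot threshold a constant set of values")
  h <- tabulate(pmin(pmax(
    as.integer((values - rng[1]) / diff(rng) * levels) + 1L, 1L), levels),
    nbins = levels)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * seq_len(levels))
  mu_t <- mu[levels]
  between <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  between[!is.finite(between)] <- -Inf
  k <- which.max(between)  # first bin of the background class boundary
  rng[1] + k / levels * diff(rng)
}

#' Compute a segmentation threshold for high-absorption vesicles
#'
#' The default strategy restricts Otsu's between-class criterion to the
#' brightest decile of voxels, so that the threshold adapts to the
#' high-density (nanoparticle-loaded) part of the histogram rather than to
#' the cytoplasm/nucleus bulk.
#'
#' @param volume an [sxt_volume()].
#' @param mode,percentile see [segmentation_params()].
#' @param exclude_mask optional [sxt_volume()] mask of voxels to leave out
#'   of the threshold computation (typically the separately segmented
#'   nucleus, whose dense chromatin would otherwise dominate the upper
#'   intensity tail in cells with few vesicles).
#' @return a single LAC threshold, strictly between the volume minimum and
#'   maximum.
#' @export
compute_threshold <- function(volume, mode = "otsu_top_decile",
                              percentile = NULL, exclude_mask = NULL) {
  v <- volume$values
  if (!is.null(exclude_mask)) v <- v[exclude_mask$values == 0]
  rng <- range(v)
  if (diff(rng) == 0)
    stop("degenerate input: volume is constant, no threshold exists")
  if (is.null(percentile))
    percentile <- if (mode == "percentile") 0.99 else 0.90
  thr <- switch(mode,
    otsu_top_decile = {
      top <- v[v >= stats::quantile(v, percentile)]
      if (diff(range(top)) == 0)
        stop("degenerate input: top-decile voxels are constant")
      otsu_threshold(top)
    },
    otsu = otsu_threshold(as.numeric(v)),
    percentile = as.numeric(stats::quantile(v, percentile)),
    stop("unknown threshold mode: ", mode))
  min(max(thr, rng[1] + .Machine$double.eps * abs(rng[1])), rng[2])
}

#' Equivalent-sphere diameter of a voxel count
#'
#' Diameter of the sphere whose volume equals `voxel_count * voxel_size^3`:
#' `d = (6 V / pi)^(1/3)`. Vesicle morphology is reduced to equivalent
#' spheres throughout the quantification.
#'
#' @param voxel_count positive integer count(s) of supra-threshold voxels.
#' @param voxel_size_nm voxel edge (nm).
#' @return diameter(s) in nm.
#' @export
#' @examples
#' equivalent_sphere_diameter(1, 10)  # ~12.41 nm
equivalent_sphere_diameter <- function(voxel_count, voxel_size_nm) {
  if (any(voxel_count < 1)) stop("'voxel_count' must be >= 1")
  if (voxel_size_nm <= 0) stop("'voxel_size_nm' must be > 0")
  (6 * voxel_count * voxel_size_nm^3 / pi)^(1 / 3)
}

#' Segment SPION-containing vesicles from a reconstructed volume
#'
#' Thresholds the volume (see [compute_threshold()]), labels connected
#' components of supra-threshold voxels, discards components with equivalent
#' diameter below `min_diameter_nm`, and reduces each remaining component to
#' an equivalent sphere at its intensity-weighted centroid. Touching
#' vesicles are not split (no watershed); see the package vignette for the
#' consequences.
#'
#' @param volume an [sxt_volume()] of LAC values.
#' @param params a [segmentation_params()].
#' @param exclude_mask optional [sxt_volume()] mask (e.g. the separately
#'   segmented nucleus): components whose intensity-weighted centroid falls
#'   inside it are dropped. Nanoparticle vesicles are never observed inside
#'   the nucleus, so supra-threshold mass there (e.g. dense chromatin in a
#'   vesicle-free cell) is not a vesicle.
#' @return list with `vesicles` (data frame: `label, x_nm, y_nm, z_nm,
#'   diameter_nm, voxel_count`), `labels` (an [sxt_volume()] of integer
#'   labels, 0 = background), and `threshold`.
#' @export
segment_vesicles <- function(volume, params = segmentation_params(),
                             exclude_mask = NULL) {
  stopifnot(inherits(volume, "sxt_volume"))
  thr <- if (identical(params$threshold_mode, "fixed")) params$threshold
         else compute_threshold(volume, params$threshold_mode, params$percentile,
                                exclude_mask = exclude_mask)
  d <- dim(volume$values)
  vox <- volume$voxel_size_nm
  mask <- volume$values > thr
  lab <- cpp_label3d(mask, d, params$connectivity)
  empty <- list(
    vesicles = data.frame(label = integer(0), x_nm = numeric(0),
                          y_nm = numeric(0), z_nm = numeric(0),
                          diameter_nm = numeric(0), voxel_count = integer(0)),
    labels = sxt_volume(array(0, d), vox), threshold = thr)
  if (max(lab) == 0L) return(empty)
  idx <- which(lab > 0L)
  li <- lab[idx]
  counts <- tabulate(li)
  keep <- which(equivalent_sphere_diameter(counts, vox) >= params$min_diameter_nm)
  if (!length(keep)) return(empty)
  # intensity-weighted centroids in physical nm
  ai <- arrayInd(idx, d)
  w <- volume$values[idx]
  sel <- li %in% keep
  li_s <- match(li[sel], keep)
  w_s <- w[sel]
  pos <- voxel_index_to_nm(ai[sel, , drop = FALSE], vox)
  wsum <- as.numeric(rowsum(w_s, li_s))
  cx <- as.numeric(rowsum(w_s * pos[, 1], li_s)) / wsum
  cy <- as.numeric(rowsum(w_s * pos[, 2], li_s)) / wsum
  cz <- as.numeric(rowsum(w_s * pos[, 3], li_s)) / wsum
  ves <- data.frame(label = seq_along(keep), x_nm = cx, y_nm = cy, z_nm = cz,
                    diameter_nm = equivalent_sphere_diameter(counts[keep], vox),
                    voxel_count = counts[keep])
  if (!is.null(exclude_mask) && nrow(ves) > 0) {
    md <- dim(exclude_mask$values)
    ijk <- cbind(pmin(pmax(ceiling(ves$x_nm / exclude_mask$voxel_size_nm), 1L), md[1]),
                 pmin(pmax(ceiling(ves$y_nm / exclude_mask$voxel_size_nm), 1L), md[2]),
                 pmin(pmax(ceiling(ves$z_nm / exclude_mask$voxel_size_nm), 1L), md[3]))
    inside <- exclude_mask$values[ijk] != 0
    keep <- keep[!inside]
    ves <- ves[!inside, , drop = FALSE]
    if (!nrow(ves)) return(empty)
    ves$label <- seq_len(nrow(ves))
  }
  relab <- integer(max(li) + 1L)
  relab[keep + 1L] <- seq_along(keep)
  newlab <- array(0L, d)
  newlab[idx] <- relab[li + 1L]
  list(vesicles = ves, labels = sxt_volume(newlab, vox), threshold = thr)
}

#' Export segmented vesicles
#'
#' `write_vesicle_set()` writes the per-vesicle CSV
#' (`label,x_nm,y_nm,z_nm,diameter_nm,voxel_count`); `write_point_model()`
#' writes a plain-text `x y z` point list (voxel units) for conversion to an
#' IMOD point model.
#'
#' @param vesicles data frame as returned in `segment_vesicles()$vesicles`.
#' @param path output path.
#' @param voxel_size_nm voxel size used to convert nm to voxel coordinates
#'   for the point model.
#' @export
write_vesicle_set <- function(vesicles, path) {
  utils::write.csv(vesicles, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_vesicle_set
#' @export
write_point_model <- function(vesicles, path, voxel_size_nm) {
  pts <- as.matrix(vesicles[, c("x_nm", "y_nm", "z_nm")]) / voxel_size_nm - 0.5
  writeLines(apply(format(pts, trim = TRUE), 1L, paste, collapse = " "), path)
  invisible(path)
}
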