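#' Tomographic volume with physical voxel size
#'
#' Light-weight container for a 3D scalar grid (typically a linear absorption
#' coefficient map in 1/um) plus its isotropic voxel size in nm. The
#' coordinate convention is: physical nm, origin at the grid corner, the
#' centre of voxel `[i, j, k]` (1-based R indices) at
#' `(i - 0.5, j - 0.5, k - 0.5) * voxel_size_nm`.
#'
#' @param values numeric 3D array; all values must be finite.
#' @param voxel_size_nm single positive number, voxel edge length in nm.
#' @return an object of class `sxt_volume` with elements `values` and
#'   `voxel_size_nm`.
#' @export
#' @examples
#' v <- sxt_volume(array(0, c(4, 4, 4)), 10)
#' dim(v)
sxt_volume <- function(values, voxel_size_nm) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("'values' must be a 3D array")
  if (!is.numeric(voxel_size_nm) || length(voxel_size_nm) != 1L ||
      !is.finite(voxel_size_nm) || voxel_size_nm <= 0)
    stop("'voxel_size_nm' must be a single positive number")
  if (anyNA(values) || !all(is.finite(values)))
    stop("volume values must be finite")
  storage.mode(values) <- "double"
  structure(list(values = values, voxel_size_nm = as.numeric(voxel_size_nm)),
            class = "sxt_volume")
}

#' @export
dim.sxt_volume <- function(x) dim(x$values)

#' @export
print.sxt_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<sxt_volume> %d x %d x %d voxels @ %.4g nm (%.3g x %.3g x %.3g um)\n",
              d[1], d[2], d[3], x$voxel_size_nm,
              d[1] * x$voxel_size_nm / 1000, d[2] * x$voxel_size_nm / 1000,
              d[3] * x$voxel_size_nm / 1000))
  cat(sprintf("  range [%.4g, %.4g], mean %.4g\n",
              min(x$values), max(x$values), mean(x$values)))
  invisible(x)
}

# physical centre coordinates (nm) of voxels along one axis
voxel_axis_nm <- function(n, voxel_size_nm) (seq_len(n) - 0.5) * voxel_size_nm

# voxel centre coordinates (nm) for a matrix of 1-based array indices
voxel_index_to_nm <- function(idx, voxel_size_nm) (idx - 0.5) * voxel_size_nm
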