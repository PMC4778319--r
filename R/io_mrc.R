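#' Read and write MRC volumes
#'
#' Minimal MRC2014 support for the volumes and tilt-series stacks this
#' package produces. `write_mrc()` always writes 32-bit float (mode 2) with
#' the voxel size recorded in the unit-cell header (`cella = n * voxel` in
#' Angstrom); `read_mrc()` accepts modes 0 (int8), 1 (int16), 2 (float32) and
#' 6 (uint16) and recovers the voxel size from `cella/mx`.
#'
#' @param volume an [sxt_volume()] (or a plain 3D array for `write_mrc`, in
#'   which case `voxel_size_nm` must be given).
#' @param path file path.
#' @param voxel_size_nm voxel size override when `volume` is a bare array.
#' @return `read_mrc()` returns an [sxt_volume()]; `write_mrc()` returns
#'   `path` invisibly.
#' @export
#' @examples
#' f <- tempfile(fileext = ".mrc")
#' write_mrc(sxt_volume(array(rnorm(8 * 8 * 4), c(8, 8, 4)), 11.5), f)
#' v <- read_mrc(f)
#' v$voxel_size_nm
write_mrc <- function(volume, path, voxel_size_nm = NULL) {
  if (inherits(volume, "sxt_volume")) {
    values <- volume$values
    vox <- volume$voxel_size_nm
  } else {
    if (is.null(voxel_size_nm))
      stop("'voxel_size_nm' is required when writing a bare array")
    values <- volume
    vox <- voxel_size_nm
  }
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("'volume' must be a 3D array")
  d <- dim(values)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4L, endian = "little")
  wi(d)                          # nx ny nz
  wi(2L)                         # mode 2 = float32
  wi(c(0L, 0L, 0L))              # nxstart nystart nzstart
  wi(d)                          # mx my mz
  wf(d * vox * 10)               # cella (Angstrom)
  wf(c(90, 90, 90))              # cellb
  wi(c(1L, 2L, 3L))              # mapc mapr maps
  wf(c(min(values), max(values), mean(values)))  # dmin dmax dmean
  wi(c(0L, 0L))                  # ispg nsymbt
  wi(integer(2L))                # extra
  writeBin(raw(4L), con)         # exttyp (none)
  wi(20140L)                     # nversion (MRC2014)
  wi(integer(21L))               # remaining extra words
  wf(c(0, 0, 0))                 # origin
  writeChar("MAP ", con, nchars = 4L, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # machst, little-endian
  wf(stats::sd(values))          # rms
  wi(1L)                         # nlabl
  lab <- sprintf("%-80s", "scvtomo")
  writeChar(lab, con, nchars = 80L, eos = NULL)
  writeBin(raw(9L * 80L), con)
  writeBin(as.numeric(values), con, size = 4L, endian = "little")
  invisible(path)
}

#' @rdname write_mrc
#' @export
read_mrc <- function(path) {
  fsize <- file.size(path)
  if (is.na(fsize) || fsize < 1024)
    stop("not a valid MRC file (shorter than the 1024-byte header): ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  ri <- function(n) readBin(con, "integer", n = n, size = 4L, endian = "little")
  rf <- function(n) readBin(con, "numeric", n = n, size = 4L, endian = "little")
  d <- ri(3L)
  mode <- ri(1L)
  ri(3L)                         # nxstart..
  m <- ri(3L)                    # mx my mz
  cella <- rf(3L)
  rf(3L)                         # cellb
  ri(3L)                         # mapc..
  rf(3L)                         # dmin dmax dmean
  ri(1L)                         # ispg
  nsymbt <- ri(1L)
  if (any(d <= 0) || any(d > 1e5))
    stop("corrupt MRC header (bad dimensions) in ", path)
  bytes <- switch(as.character(mode), "0" = 1L, "1" = 2L, "2" = 4L, "6" = 2L, NULL)
  if (is.null(bytes))
    stop("unsupported MRC mode ", mode, " in ", path)
  n <- prod(d)
  expected <- 1024 + as.numeric(nsymbt) + as.numeric(n) * bytes
  if (fsize < expected)
    stop(sprintf("truncated MRC file %s: %d bytes, expected %d", path,
                 fsize, as.integer(expected)))
  seek(con, 1024 + nsymbt)
  values <- switch(as.character(mode),
    "0" = as.numeric(readBin(con, "integer", n = n, size = 1L, signed = TRUE)),
    "1" = as.numeric(readBin(con, "integer", n = n, size = 2L,
                             signed = TRUE, endian = "little")),
    "2" = readBin(con, "numeric", n = n, size = 4L, endian = "little"),
    "6" = as.numeric(readBin(con, "integer", n = n, size = 2L,
                             signed = FALSE, endian = "little")))
  vox <- if (all(m > 0) && all(cella > 0)) cella[1] / m[1] / 10 else 1
  sxt_volume(array(values, d), vox)
}

#' Read and write tilt-angle files
#'
#' Plain-text tilt angle files, one angle in degrees per line (the IMOD
#' `.tlt` dialect).
#'
#' @param angles_deg numeric vector of angles in degrees.
#' @param path file path.
#' @return `read_tilt_angles()` returns a numeric vector; `write_tilt_angles()`
#'   returns `path` invisibly.
#' @export
write_tilt_angles <- function(angles_deg, path) {
  writeLines(formatC(angles_deg, format = "f", digits = 2), path)
  invisible(path)
}

#' @rdname write_tilt_angles
#' @export
read_tilt_angles <- function(path) {
  as.numeric(readLines(path))
}
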