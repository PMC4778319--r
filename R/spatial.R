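#' Distance from vesicle centres to the nuclear surface
#'
#' Euclidean distance from each centre to the nearest nucleus-surface voxel
#' centre, in um. Surface voxels are mask voxels with at least one
#' 6-neighbour outside the mask. Centres found inside the nucleus are
#' flagged with a negative distance and a warning: intracellular
#' nanoparticle vesicles are never observed inside the nucleus, so an
#' interior centre indicates a segmentation or registration problem.
#'
#' @param centres_nm n x 3 matrix (or data frame with columns
#'   `x_nm, y_nm, z_nm`) of centre positions in nm.
#' @param nucleus_mask an [sxt_volume()] with non-zero values inside the
#'   nucleus.
#' @return numeric vector of distances in um (negative for interior centres).
#' @export
distance_to_nucleus <- function(centres_nm, nucleus_mask) {
  stopifnot(inherits(nucleus_mask, "sxt_volume"))
  centres_nm <- centres_matrix(centres_nm)
  m <- nucleus_mask$values != 0
  if (!any(m)) stop("nucleus mask is empty")
  d <- dim(m)
  vox <- nucleus_mask$voxel_size_nm
  surf <- mask_surface(m)
  si <- which(surf)
  sp <- voxel_index_to_nm(arrayInd(si, d), vox)
  n <- nrow(centres_nm)
  out <- numeric(n)
  inside <- logical(n)
  for (i in seq_len(n)) {
    p <- centres_nm[i, ]
    out[i] <- sqrt(min((sp[, 1] - p[1])^2 + (sp[, 2] - p[2])^2 +
                       (sp[, 3] - p[3])^2))
    ijk <- pmin(pmax(ceiling(p / vox), 1L), d)
    inside[i] <- m[ijk[1], ijk[2], ijk[3]]
  }
  if (any(inside)) {
    warning(sum(inside), " centre(s) lie inside the nucleus; ",
            "their distances are reported as negative")
    out[inside] <- -out[inside]
  }
  out / 1000
}

# voxels of m with at least one 6-neighbour outside m (volume faces count as
# outside, so a mask touching the boundary still has a surface there)
mask_surface <- function(m) {
  d <- dim(m)
  pad <- array(FALSE, d + 2L)
  pad[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)] <- m
  core <- pad[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)]
  nb <- pad[1:d[1], 2:(d[2] + 1L), 2:(d[3] + 1L)] &
        pad[3:(d[1] + 2L), 2:(d[2] + 1L), 2:(d[3] + 1L)] &
        pad[2:(d[1] + 1L), 1:d[2], 2:(d[3] + 1L)] &
        pad[2:(d[1] + 1L), 3:(d[2] + 2L), 2:(d[3] + 1L)] &
        pad[2:(d[1] + 1L), 2:(d[2] + 1L), 1:d[3]] &
        pad[2:(d[1] + 1L), 2:(d[2] + 1L), 3:(d[3] + 2L)]
  core & !nb
}

centres_matrix <- function(centres) {
  if (is.data.frame(centres)) {
    if (all(c("x_nm", "y_nm", "z_nm") %in% names(centres)))
      centres <- centres[, c("x_nm", "y_nm", "z_nm")]
    centres <- as.matrix(centres)
  }
  centres <- matrix(as.numeric(centres), ncol = 3L)
  if (anyNA(centres)) stop("centres contain NA")
  centres
}

#' Mean distance to the k nearest neighbouring vesicles
#'
#' For each vesicle centre, the mean Euclidean distance to its `k` nearest
#' *other* centres (default `k = 4`, the neighbourhood used to characterise
#' crowding in the perinuclear accumulation area). If fewer than `k` other
#' centres exist the mean is taken over all of them and the record is
#' flagged. Distance ties are broken by ascending index; duplicate centres
#' contribute zero distances.
#'
#' @param centres_nm n x 3 matrix (nm), n >= 2.
#' @param k neighbour count (default 4).
#' @return numeric vector of per-vesicle mean distances (nm), with attribute
#'   `"flagged"` (logical vector, TRUE where fewer than `k` neighbours were
#'   available).
#' @export
knn_mean_distance <- function(centres_nm, k = 4) {
  centres_nm <- centres_matrix(centres_nm)
  n <- nrow(centres_nm)
  if (n < 2) stop("at least 2 centres are needed for a neighbour distance")
  if (k < 1) stop("'k' must be >= 1")
  dm <- as.matrix(stats::dist(centres_nm))
  kk <- min(k, n - 1L)
  out <- numeric(n)
  for (i in seq_len(n)) {
    di <- dm[i, -i]
    sel <- order(di, seq_along(di))[seq_len(kk)]
    out[i] <- mean(di[sel])
  }
  attr(out, "flagged") <- rep(kk < k, n)
  out
}

#' Accumulated vesicle volume
#'
#' Total volume of the equivalent spheres, `sum(pi/6 * d^3)`, in um^3.
#'
#' @param diameters_nm vesicle diameters in nm (all >= 0).
#' @return volume in um^3 (0 for an empty set).
#' @export
#' @examples
#' accumulated_volume(570)  # ~0.097 um^3
accumulated_volume <- function(diameters_nm) {
  if (any(diameters_nm < 0)) stop("diameters must be >= 0")
  sum(pi / 6 * (diameters_nm / 1000)^3)
}

#' Vesicle volume as a fraction of the cell volume
#'
#' @param scv_volume_um3 accumulated vesicle volume (um^3).
#' @param cell_volume_um3 cell volume (um^3), > 0.
#' @return percentage, `100 * scv_volume / cell_volume`.
#' @export
#' @examples
#' volume_fraction(20, 2000)  # 1 percent
volume_fraction <- function(scv_volume_um3, cell_volume_um3) {
  if (any(cell_volume_um3 <= 0)) stop("'cell_volume_um3' must be > 0")
  100 * scv_volume_um3 / cell_volume_um3
}

#' Cylinder model of an adherent cell's volume
#'
#' Adherent cells on a flat support are approximated as a cylinder of the
#' given diameter and thickness: `V = pi (d/2)^2 h`.
#'
#' @param diameter_um cell diameter (um), > 0.
#' @param thickness_um cell thickness (um), > 0.
#' @return volume in um^3.
#' @export
#' @examples
#' cell_volume_model(20, 5)  # ~1570.8 um^3
cell_volume_model <- function(diameter_um = 20, thickness_um = 5) {
  if (diameter_um <= 0 || thickness_um <= 0)
    stop("cell diameter and thickness must be > 0")
  pi * (diameter_um / 2)^2 * thickness_um
}

#' Vesicle size classes
#'
#' The colour-coded size model distinguishes small (< 600 nm), medium
#' (600-1000 nm) and large (>= 1000 nm) vesicles; boundaries are half-open
#' (`[lower, upper)`), so a 600 nm vesicle is medium.
#'
#' @return data frame with columns `name, lower_nm, upper_nm` partitioning
#'   the positive axis.
#' @export
size_classes <- function() {
  data.frame(name = c("small", "medium", "large"),
             lower_nm = c(0, 600, 1000),
             upper_nm = c(600, 1000, Inf),
             stringsAsFactors = FALSE)
}

#' Assign a size class to each diameter
#'
#' @param diameter_nm vesicle diameters (nm), all > 0.
#' @param classes a size-class table as from [size_classes()].
#' @return character vector of class names.
#' @export
#' @examples
#' assign_size_class(c(500, 600, 1100))
assign_size_class <- function(diameter_nm, classes = size_classes()) {
  if (any(diameter_nm <= 0)) stop("diameters must be > 0")
  if (any(classes$lower_nm[-1] != classes$upper_nm[-nrow(classes)]) ||
      classes$lower_nm[1] != 0 || !is.infinite(classes$upper_nm[nrow(classes)]))
    stop("size classes must partition (0, Inf)")
  idx <- findInterval(diameter_nm, classes$lower_nm)
  classes$name[idx]
}
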