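# shared in-code fixtures: everything is generated at test time

# a small two-sphere phantom without nucleus, on an isotropic grid
two_sphere_phantom <- function(d1 = 500, d2 = 700, sep_nm = 2000,
                               voxel = 20, pad = 600) {
  ex <- c(d1 + d2 + sep_nm + 2 * pad, max(d1, d2) + 2 * pad,
          max(d1, d2) + 2 * pad)
  ves <- data.frame(
    x_nm = c(pad + d1 / 2, pad + d1 / 2 + sep_nm + (d1 + d2) / 2),
    y_nm = ex[2] / 2, z_nm = ex[3] / 2,
    diameter_nm = c(d1, d2))
  cell_phantom(NULL, ves, background_lac = 0.3, extent_nm = ex)
}

# spherical "nucleus" mask volume for distance tests
sphere_mask <- function(radius_nm, centre_nm, dim, voxel) {
  ax <- (seq_len(dim[1]) - 0.5) * voxel
  ay <- (seq_len(dim[2]) - 0.5) * voxel
  az <- (seq_len(dim[3]) - 0.5) * voxel
  m <- array(0, dim)
  for (k in seq_len(dim[3])) {
    m[, , k] <- (outer((ax - centre_nm[1])^2, (ay - centre_nm[2])^2, "+") +
                 (az[k] - centre_nm[3])^2) <= radius_nm^2
  }
  sxt_volume(m * 1, voxel)
}

# brute-force mean k-NN distance, independent double loop over all pairs
brute_knn <- function(p, k = 4) {
  n <- nrow(p)
  out <- numeric(n)
  for (i in seq_len(n)) {
    d <- numeric(0)
    for (j in seq_len(n)) {
      if (i == j) next
      d <- c(d, sqrt(sum((p[i, ] - p[j, ])^2)))
    }
    out[i] <- mean(sort(d)[seq_len(min(k, n - 1L))])
  }
  out
}

# exhaustive-scan Otsu oracle: maximize between-class variance over every
# midpoint between consecutive sorted unique values
scan_threshold <- function(x) {
  u <- sort(unique(x))
  cand <- (u[-1] + u[-length(u)]) / 2
  best <- -Inf
  bt <- cand[1]
  for (t in cand) {
    a <- x[x <= t]
    b <- x[x > t]
    w <- length(a) / length(x)
    v <- w * (1 - w) * (mean(a) - mean(b))^2
    if (v > best) {
      best <- v
      bt <- t
    }
  }
  bt
}

# noiseless image-and-reconstruct of a phantom at its native voxel size
image_and_reconstruct <- function(phantom, voxel, iterations = 30,
                                  step = 1, range_deg = c(-70, 70)) {
  vol <- voxelize_phantom(phantom, voxel)
  g <- make_tilt_geometry(range_deg[1], range_deg[2], step, voxel)
  absorb <- normalize_flatfield(project_tilt_series(vol, g))
  reconstruct_sirt(absorb, g, dim(vol$values), iterations = iterations)
}
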