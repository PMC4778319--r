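test_that("nucleus distance matches the analytic sphere", {
  vox <- 200
  dimv <- c(64, 64, 64)
  ctr <- dimv * vox / 2
  mask <- sphere_mask(5000, ctr, dimv, vox)
  p_out <- ctr + c(8000, 0, 0)
  p_surf <- ctr + c(5000, 0, 0)
  d1 <- distance_to_nucleus(rbind(p_out), mask)
  expect_lt(abs(d1 - 3.0), vox / 1000)
  # a point exactly on the surface sits in a boundary voxel of the mask, so
  # it is flagged; its unsigned distance is still ~0
  expect_warning(d2 <- distance_to_nucleus(rbind(p_surf), mask),
                 "inside the nucleus")
  expect_lt(abs(abs(d2) - 0.0), vox / 1000)
  expect_warning(din <- distance_to_nucleus(rbind(ctr + c(1000, 0, 0)), mask),
                 "inside the nucleus")
  expect_lt(din, 0)
  expect_error(distance_to_nucleus(rbind(p_out),
                                   sxt_volume(array(0, c(4, 4, 4)), 100)),
               "empty")
})

test_that("voxelized ellipsoid distance agrees with the analytic one", {
  vox <- 100
  dimv <- c(80, 80, 50)
  ctr <- dimv * vox / 2
  nuc <- nucleus_model(ctr, c(2200, 1800, 1100))
  ph <- cell_phantom(nuc, data.frame(), extent_nm = dimv * vox)
  mask <- voxelize_nucleus_mask(ph, vox)
  set.seed(3)
  pts <- ctr + cbind(runif(8, -3500, 3500), runif(8, -3500, 3500),
                     runif(8, -1200, 1200))
  keep <- !is.na(ellipsoid_surface_distance(pts, nuc))
  pts <- pts[keep, , drop = FALSE]
  d_mask <- distance_to_nucleus(pts, mask) * 1000
  d_true <- ellipsoid_surface_distance(pts, nuc)
  expect_true(all(abs(d_mask - d_true) <= vox))
})

test_that("kNN mean distance matches the hand-checked cross configuration", {
  p <- rbind(c(0, 0, 0), c(400, 0, 0), c(-400, 0, 0), c(0, 400, 0),
             c(0, -400, 0))
  nn <- knn_mean_distance(p, k = 4)
  expect_equal(nn[1], 400)
  # fewer than k neighbours: computed over what exists, flagged
  p3 <- p[1:3, ]
  nn3 <- knn_mean_distance(p3, k = 4)
  expect_equal(as.numeric(nn3[1]), 400)
  expect_true(all(attr(nn3, "flagged")))
  # duplicates contribute zero distances without error
  pd <- rbind(c(0, 0, 0), c(0, 0, 0), c(300, 0, 0))
  nnd <- knn_mean_distance(pd, k = 1)
  expect_equal(as.numeric(nnd[1:2]), c(0, 0))
  expect_error(knn_mean_distance(p[1, , drop = FALSE]), "at least 2")
})

test_that("kNN means equal the brute-force all-pairs oracle", {
  set.seed(17)
  for (rep in 1:5) {
    n <- sample(5:60, 1)
    p <- matrix(runif(3 * n, 0, 5000), ncol = 3)
    expect_equal(as.numeric(knn_mean_distance(p, k = 4)), brute_knn(p, 4),
                 tolerance = 1e-12)
  }
})

test_that("accumulated volume follows the closed form and is additive", {
  expect_equal(accumulated_volume(570), pi / 6 * 0.57^3)
  expect_equal(accumulated_volume(570), 0.09697, tolerance = 1e-4)
  expect_identical(accumulated_volume(numeric(0)), 0)
  # 160 vesicles of 620 nm: ~20 um^3 accumulated volume
  expect_equal(accumulated_volume(rep(620, 160)), 19.96, tolerance = 1e-3)
  a <- c(300, 500); b <- c(700, 900)
  expect_equal(accumulated_volume(c(a, b)),
               accumulated_volume(a) + accumulated_volume(b))
  expect_error(accumulated_volume(-5), ">= 0")
})

test_that("volume fraction and the cylinder cell model are exact", {
  expect_identical(volume_fraction(20, 2000), 1)
  expect_identical(volume_fraction(0, 1234), 0)
  expect_identical(volume_fraction(55, 55), 100)
  expect_error(volume_fraction(20, 0), "> 0")
  expect_equal(cell_volume_model(20, 5), 1570.8, tolerance = 1e-4)
  expect_equal(cell_volume_model(20, 3), 942.48, tolerance = 1e-4)
  expect_equal(cell_volume_model(2, 1), pi)
  expect_error(cell_volume_model(-20, 5), "> 0")
})

test_that("size classes partition diameters with half-open bounds", {
  expect_identical(assign_size_class(c(500, 600, 1100)),
                   c("small", "medium", "large"))
  expect_identical(assign_size_class(999.9), "medium")
  expect_identical(assign_size_class(1000), "large")
  expect_error(assign_size_class(0), "> 0")
  bad <- data.frame(name = c("a", "b"), lower_nm = c(0, 700),
                    upper_nm = c(600, Inf))
  expect_error(assign_size_class(500, bad), "partition")
})

test_that("summarize_cell equals an independent recomputation", {
  vox <- 200
  dimv <- c(64, 64, 64)
  ctr <- dimv * vox / 2
  mask <- sphere_mask(4000, ctr, dimv, vox)
  ves <- data.frame(
    x_nm = ctr[1] + c(5200, -5400, 0, 0),
    y_nm = ctr[2] + c(0, 300, 5600, -5100),
    z_nm = ctr[3] + c(200, -150, 100, 0),
    diameter_nm = c(300, 450, 600, 900))
  s <- summarize_cell(ves, mask, condition = "test",
                      cell_volume_um3 = 1000)
  expect_equal(s$n_vesicles, 4)
  expect_equal(s$diam_nm_avg, mean(ves$diameter_nm))
  expect_equal(s$diam_nm_max, 900)
  expect_equal(s$diam_nm_min, 300)
  expect_equal(s$diam_nm_sd, sd(ves$diameter_nm))
  nd <- distance_to_nucleus(ves, mask)
  expect_equal(s$ndist_um_avg, mean(nd))
  expect_equal(s$ndist_um_sd, sd(nd))
  nn <- brute_knn(as.matrix(ves[, 1:3]), 4)
  expect_equal(s$nn_nm_avg, mean(nn))
  expect_equal(s$accumulated_volume_um3,
               sum(pi / 6 * (ves$diameter_nm / 1000)^3))
  expect_equal(s$volume_fraction_pct, 100 * s$accumulated_volume_um3 / 1000)
})

test_that("degenerate vesicle sets summarize sensibly", {
  one <- data.frame(x_nm = 1, y_nm = 1, z_nm = 1, diameter_nm = 500)
  s1 <- summarize_cell(one, NULL, condition = "x")
  expect_equal(s1$n_vesicles, 1)
  expect_equal(s1$diam_nm_avg, 500)
  expect_equal(s1$diam_nm_min, s1$diam_nm_max)
  expect_true(is.na(s1$diam_nm_sd))
  s0 <- summarize_cell(one[0, ], NULL, condition = "x")
  expect_equal(s0$n_vesicles, 0)
  expect_true(is.na(s0$diam_nm_avg))
  expect_equal(s0$accumulated_volume_um3, 0)
})

test_that("condition aggregation averages cells and guards mixed input", {
  one <- data.frame(x_nm = 1:4 * 1000, y_nm = 1, z_nm = 1,
                    diameter_nm = c(400, 500, 600, 700))
  s <- summarize_cell(one, NULL, condition = "12h")
  agg <- aggregate_condition(list(s, s, s, s, s))
  expect_equal(agg$n_cells, 5)
  expect_equal(agg$diam_nm_avg_mean, s$diam_nm_avg)
  expect_equal(agg$diam_nm_avg_cellsd, 0)
  a <- s; a$n_vesicles <- 80
  b <- s; b$n_vesicles <- 90
  expect_equal(aggregate_condition(list(a, b))$n_vesicles_mean, 85)
  bad <- s; bad$condition <- "24h"
  expect_error(aggregate_condition(list(s, bad)), "mix")
})

test_that("distance statistics are invariant under rigid motion", {
  vox <- 200
  dimv <- c(48, 48, 48)
  ctr <- dimv * vox / 2
  mask <- sphere_mask(3000, ctr, dimv, vox)
  set.seed(31)
  ang <- runif(12, 0, 2 * pi)
  u <- cbind(cos(ang) * runif(12, 0.5, 1), sin(ang) * runif(12, 0.5, 1),
             runif(12, -0.3, 0.3))
  pts <- ctr + 4500 * u / sqrt(rowSums(u^2))
  d0 <- distance_to_nucleus(pts, mask)
  nn0 <- knn_mean_distance(pts)
  # translate mask and points by a whole number of voxels
  shift <- c(3, -2, 4) * vox
  mshift <- array(0, dimv)
  mshift[(1 + 3):dimv[1], 1:(dimv[2] - 2), (1 + 4):dimv[3]] <-
    mask$values[1:(dimv[1] - 3), 3:dimv[2], 1:(dimv[3] - 4)]
  d1 <- distance_to_nucleus(sweep(pts, 2, -shift), sxt_volume(mshift, vox))
  expect_true(all(abs(d1 - d0) * 1000 <= vox))
  expect_equal(as.numeric(knn_mean_distance(sweep(pts, 2, -shift))),
               as.numeric(nn0))
  # rotate 90 degrees about z: (x, y) -> (y, -x) about the volume centre
  rot <- cbind(pts[, 2], 2 * ctr[1] - pts[, 1], pts[, 3])
  mrot <- aperm(mask$values, c(2, 1, 3))[, dimv[1]:1, ]
  d2 <- distance_to_nucleus(rot, sxt_volume(mrot, vox))
  expect_true(all(abs(d2 - d0) * 1000 <= vox))
  expect_equal(as.numeric(knn_mean_distance(rot)), as.numeric(nn0))
})
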