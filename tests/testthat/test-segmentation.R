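test_that("threshold lies strictly between the class levels", {
  v <- array(0.3, c(20, 20, 10))
  v[8:12, 8:12, 4:6] <- 1.0
  thr <- compute_threshold(sxt_volume(v, 50))
  expect_gt(thr, 0.3)
  expect_lt(thr, 1.0)
  expect_error(compute_threshold(sxt_volume(array(0.5, c(8, 8, 8)), 50)),
               "degenerate")
})

test_that("Otsu matches an exhaustive between-class scan on a bimodal mixture", {
  # overlapping modes, so the between-class optimum is well conditioned
  set.seed(13)
  x <- c(rnorm(6000, 0.40, 0.09), rnorm(2000, 0.85, 0.10))
  v <- sxt_volume(array(x, c(20, 20, 20)), 50)
  thr <- compute_threshold(v, mode = "otsu")
  oracle <- scan_threshold(x)
  expect_lt(abs(thr - oracle) / oracle, 0.05)
})

test_that("two well-separated spheres segment into two accurate records", {
  ph <- two_sphere_phantom(d1 = 500, d2 = 700, sep_nm = 2000, voxel = 20)
  vol <- voxelize_phantom(ph, 20)
  seg <- segment_vesicles(vol)
  expect_equal(nrow(seg$vesicles), 2)
  got <- seg$vesicles[order(seg$vesicles$diameter_nm), ]
  expect_equal(got$diameter_nm, c(500, 700), tolerance = 0.02)
  for (i in 1:2) {
    truth <- unlist(ph$vesicles[i, c("x_nm", "y_nm", "z_nm")])
    rec <- unlist(got[i, c("x_nm", "y_nm", "z_nm")])
    expect_lt(sqrt(sum((rec - truth)^2)), 20)  # within one voxel
  }
  # idempotent and deterministic
  seg2 <- segment_vesicles(vol)
  expect_identical(seg$vesicles, seg2$vesicles)
  expect_identical(seg$labels$values, seg2$labels$values)
})

test_that("the minimum-diameter filter drops sub-resolution components", {
  ves <- data.frame(x_nm = 500, y_nm = 500, z_nm = 500, diameter_nm = 80)
  ph <- cell_phantom(NULL, ves, background_lac = 0.3, extent_nm = rep(1000, 3))
  vol <- voxelize_phantom(ph, 10)
  seg <- segment_vesicles(vol, segmentation_params(min_diameter_nm = 100))
  expect_equal(nrow(seg$vesicles), 0)
  seg2 <- segment_vesicles(vol, segmentation_params(min_diameter_nm = 0))
  expect_equal(nrow(seg2$vesicles), 1)
})

test_that("an all-background volume yields an empty vesicle set", {
  v <- array(0.3, c(16, 16, 8))
  v[1, 1, 1] <- 0.31  # non-constant but featureless
  seg <- segment_vesicles(sxt_volume(v, 50))
  expect_equal(nrow(seg$vesicles), 0)
})

test_that("equivalent-sphere diameter follows the closed form and scaling law", {
  expect_equal(equivalent_sphere_diameter(1, 10), (6000 / pi)^(1 / 3),
               tolerance = 1e-12)
  expect_equal(equivalent_sphere_diameter(1, 10), 12.407, tolerance = 1e-4)
  expect_equal(equivalent_sphere_diameter(345, 20),
               2 * equivalent_sphere_diameter(345, 10))
  expect_error(equivalent_sphere_diameter(0, 10), ">= 1")
  # inversion: voxel count of a d = 570 nm sphere recovers 570 within 2%
  ves <- data.frame(x_nm = 400, y_nm = 400, z_nm = 400, diameter_nm = 570,
                    lac = 1)
  ph <- cell_phantom(NULL, ves, background_lac = 0, extent_nm = rep(800, 3))
  vol <- voxelize_phantom(ph, 10)
  count <- sum(vol$values > 0.5)
  expect_equal(equivalent_sphere_diameter(count, 10), 570, tolerance = 0.02)
})

test_that("raising the threshold never grows any component", {
  set.seed(5)
  base <- array(0.3 + 0.02 * rnorm(24^3), c(24, 24, 24))
  ves <- data.frame(x_nm = c(600, 1600), y_nm = 1200, z_nm = 1200,
                    diameter_nm = c(500, 700))
  ph <- cell_phantom(NULL, ves, background_lac = 0.3, extent_nm = rep(2400, 3))
  v <- voxelize_phantom(ph, 100)
  v$values <- v$values + 0.05 * array(rnorm(length(v$values)), dim(v$values))
  lo <- segment_vesicles(v, segmentation_params("fixed", threshold = 0.55,
                                                min_diameter_nm = 0))
  hi <- segment_vesicles(v, segmentation_params("fixed", threshold = 0.70,
                                                min_diameter_nm = 0))
  # every high-threshold component sits inside one low-threshold component
  for (i in seq_len(nrow(hi$vesicles))) {
    vox_hi <- which(hi$labels$values == hi$vesicles$label[i])
    parents <- unique(lo$labels$values[vox_hi])
    expect_length(parents, 1)
    expect_lte(hi$vesicles$voxel_count[i],
               lo$vesicles$voxel_count[lo$vesicles$label == parents])
  }
})

test_that("components inside the exclusion mask are not reported as vesicles", {
  nuc <- nucleus_model(c(1500, 1500, 1500), c(700, 700, 500), lac = 0.9)
  ves <- data.frame(x_nm = 4000, y_nm = 1500, z_nm = 1500, diameter_nm = 500)
  ph <- cell_phantom(nuc, ves, background_lac = 0.3, extent_nm = c(5000, 3000, 3000))
  vol <- voxelize_phantom(ph, 50)
  mask <- voxelize_nucleus_mask(ph, 50)
  plain <- segment_vesicles(vol, segmentation_params("fixed", threshold = 0.6))
  masked <- segment_vesicles(vol, segmentation_params("fixed", threshold = 0.6),
                             exclude_mask = mask)
  expect_equal(nrow(plain$vesicles), 2)
  expect_equal(nrow(masked$vesicles), 1)
  expect_equal(masked$vesicles$diameter_nm, 500, tolerance = 0.05)
})

test_that("the imaging chain recovers counts and diameters at fine voxels", {
  # headline pipeline property at the 22 nm desk voxel: exact count,
  # median diameter error within 15% for d >= 200 nm, centres within 1 voxel
  vox <- 22
  dimv <- c(96, 96, 64)
  ex <- dimv * vox
  ves <- data.frame(
    x_nm = c(420, 1130, 1750, 520, 1500),
    y_nm = c(450, 500, 1300, 1500, 1650),
    z_nm = c(480, 780, 600, 820, 500),
    diameter_nm = c(200, 420, 570, 350, 260))
  ph <- cell_phantom(NULL, ves, background_lac = 0.3, extent_nm = ex)
  rec <- image_and_reconstruct(ph, vox)
  seg <- segment_vesicles(rec)
  expect_equal(nrow(seg$vesicles), nrow(ves))
  got <- seg$vesicles
  match_idx <- vapply(seq_len(nrow(ves)), function(i) {
    which.min((got$x_nm - ves$x_nm[i])^2 + (got$y_nm - ves$y_nm[i])^2 +
              (got$z_nm - ves$z_nm[i])^2)
  }, integer(1))
  expect_identical(sort(match_idx), seq_len(nrow(ves)))
  cerr <- sqrt((got$x_nm[match_idx] - ves$x_nm)^2 +
               (got$y_nm[match_idx] - ves$y_nm)^2 +
               (got$z_nm[match_idx] - ves$z_nm)^2)
  expect_true(all(cerr <= vox))
  rel_err <- abs(got$diameter_nm[match_idx] - ves$diameter_nm) / ves$diameter_nm
  expect_lte(median(rel_err), 0.15)
})
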