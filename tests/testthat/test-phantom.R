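test_that("diameter sampling respects truncation bounds and edge cases", {
  d <- sample_vesicle_diameters(1000, mean_nm = 570, sd_nm = 96,
                                bounds_nm = c(100, 1000), seed = 11)
  expect_length(d, 1000)
  expect_true(all(d >= 100 & d <= 1000))
  expect_identical(sample_vesicle_diameters(0, 570, 96), numeric(0))
  expect_identical(sample_vesicle_diameters(50, 570, 96, seed = 3),
                   sample_vesicle_diameters(50, 570, 96, seed = 3))
  expect_error(sample_vesicle_diameters(10, 570, -1), "sd")
  expect_error(sample_vesicle_diameters(10, 570, 96, bounds_nm = c(900, 100)))
})

test_that("sample mean matches a Monte-Carlo estimate of the truncated mean", {
  # independent oracle: plain lognormal draws filtered to the bounds
  mean_nm <- 570; sd_nm <- 96; bounds <- c(100, 1000)
  sigma2 <- log(1 + (sd_nm / mean_nm)^2)
  mu <- log(mean_nm) - sigma2 / 2
  set.seed(42)
  big <- rlnorm(4e5, mu, sqrt(sigma2))
  big <- big[big >= bounds[1] & big <= bounds[2]]
  oracle_mean <- mean(big)
  oracle_sd <- sd(big)
  d <- sample_vesicle_diameters(1000, mean_nm, sd_nm, bounds, seed = 7)
  expect_lt(abs(mean(d) - oracle_mean), 3 * oracle_sd / sqrt(1000))
})

test_that("generated diameters emulate the 12 h statistics over many seeds", {
  # condition targets: mean 570 nm, SD 70 nm, ~160 vesicles per cell
  n <- 160; reps <- 20
  pooled <- unlist(lapply(seq_len(reps), function(s)
    sample_vesicle_diameters(n, 570, 70, seed = s)))
  se_mean <- 70 / sqrt(n * reps)
  expect_lt(abs(mean(pooled) - 570), 3 * se_mean)
  # SE of a sample SD ~ sd / sqrt(2 (n-1))
  expect_lt(abs(sd(pooled) - 70), 3 * 70 / sqrt(2 * (n * reps - 1)))
})

test_that("placement honours the shell, separation and determinism contracts", {
  # spherical nucleus so the surface distance has a closed form
  nuc <- nucleus_model(c(6000, 6000, 6000), c(1500, 1500, 1500))
  spec <- placement_spec(10, shell_nm = c(2300, 3800), min_separation_nm = 325,
                         min_surface_gap_nm = 250)
  diam <- sample_vesicle_diameters(10, 570, 70, seed = 2)
  p <- place_vesicles(nuc, spec, diam, extent_nm = c(12000, 12000, 12000),
                      seed = 5)
  surf <- sqrt(rowSums(sweep(p, 2, nuc$centre_nm)^2)) - 1500
  expect_true(all(surf >= 2300 & surf <= 3800))
  dm <- as.matrix(dist(p)); diag(dm) <- Inf
  need <- outer(diam, diam, function(a, b) pmax(325, (a + b) / 2 + 250))
  expect_true(all(dm >= need - 1e-9))
  expect_identical(p, place_vesicles(nuc, spec, diam,
                                     c(12000, 12000, 12000), seed = 5))
})

test_that("infeasible packing raises a placement error naming progress", {
  nuc <- nucleus_model(c(4000, 4000, 4000), c(1000, 1000, 1000))
  spec <- placement_spec(10000, shell_nm = c(500, 1500),
                         min_separation_nm = 500, attempts_per_vesicle = 200)
  diam <- rep(300, 10000)
  err <- tryCatch(place_vesicles(nuc, spec, diam, c(8000, 8000, 8000), seed = 1),
                  error = identity)
  expect_s3_class(err, "scv_placement_error")
  expect_match(conditionMessage(err), "of 10000 vesicles")
})

test_that("phantom construction enforces its invariants", {
  nuc <- nucleus_model(c(5000, 5000, 5000), c(2000, 2000, 2000))
  inside <- data.frame(x_nm = 5000, y_nm = 5000, z_nm = 6000, diameter_nm = 400)
  expect_error(cell_phantom(nuc, inside, extent_nm = rep(10000, 3)),
               "outside the nucleus")
  low <- data.frame(x_nm = 1000, y_nm = 1000, z_nm = 1000, diameter_nm = 400,
                    lac = 0.2)
  expect_error(cell_phantom(NULL, low, background_lac = 0.3,
                            extent_nm = rep(10000, 3)), "exceed")
  expect_error(nucleus_model(c(0, 0, 0), c(1000, -1, 1000)), "> 0")
})

test_that("sphere voxelization matches the closed-form volume", {
  ves <- data.frame(x_nm = 1000, y_nm = 1000, z_nm = 1000, diameter_nm = 570,
                    lac = 1)
  ph <- cell_phantom(NULL, ves, background_lac = 0, extent_nm = rep(2000, 3))
  v <- voxelize_phantom(ph, 10)
  count <- sum(v$values == 1)
  expect_lt(abs(count - pi / 6 * 57^3) / (pi / 6 * 57^3), 0.02)
})

test_that("voxelization is consistent across detector pixel sizes", {
  ves <- data.frame(x_nm = 3000, y_nm = 3000, z_nm = 3000, diameter_nm = 570)
  ph <- cell_phantom(NULL, ves, background_lac = 0.1, extent_nm = rep(6000, 3))
  vols <- vapply(c(11.5, 15.56), function(vox) {
    v <- voxelize_phantom(ph, vox)
    sum(v$values == ph$vesicles$lac[1]) * (vox / 1000)^3
  }, numeric(1))
  expect_lt(abs(vols[1] - vols[2]) / vols[1], 0.05)
})

test_that("a vesicle-free phantom voxelizes to background plus nucleus only", {
  nuc <- nucleus_model(c(2000, 2000, 2000), c(800, 700, 600), lac = 0.4)
  ph <- cell_phantom(nuc, data.frame(), background_lac = 0.3,
                     extent_nm = rep(4000, 3))
  v <- voxelize_phantom(ph, 50)
  expect_true(all(v$values %in% c(0.3, 0.4)))
  mask <- voxelize_nucleus_mask(ph, 50)
  expect_identical(unname(v$values == 0.4), unname(mask$values == 1))
})

test_that("phantom generation is deterministic and truth volume is closed form", {
  cond <- scv_conditions()[1, ]  # control: few vesicles, fast
  ex <- c(128, 128, 48) * 105
  ph1 <- generate_cell_phantom(cond, ex, seed = 4)
  ph2 <- generate_cell_phantom(cond, ex, seed = 4)
  expect_identical(ph1$vesicles, ph2$vesicles)
  expect_equal(accumulated_volume(ph1$vesicles$diameter_nm),
               sum(pi / 6 * (ph1$vesicles$diameter_nm / 1000)^3))
  # truth CSV roundtrip
  f <- tempfile(fileext = ".csv")
  write_vesicle_truth(ph1, f)
  back <- read_vesicle_truth(f)
  expect_equal(back$diameter_nm, ph1$vesicles$diameter_nm, tolerance = 1e-6)
})

test_that("analytic ellipsoid distance agrees with direct minimization", {
  nuc <- nucleus_model(c(0, 0, 0), c(2200, 1800, 1100))
  set.seed(9)
  pts <- matrix(runif(30, -6000, 6000), ncol = 3)
  d_pkg <- ellipsoid_surface_distance(pts, nuc)
  for (i in seq_len(nrow(pts))) {
    q2 <- sum((pts[i, ] / nuc$semi_axes_nm)^2)
    if (q2 <= 1) {
      expect_true(is.na(d_pkg[i]))
      next
    }
    # oracle: minimize |surface(theta, phi) - p| over spherical angles
    obj <- function(ang) {
      s <- c(nuc$semi_axes_nm[1] * cos(ang[1]) * cos(ang[2]),
             nuc$semi_axes_nm[2] * sin(ang[1]) * cos(ang[2]),
             nuc$semi_axes_nm[3] * sin(ang[2]))
      sqrt(sum((s - pts[i, ])^2))
    }
    o <- optim(c(atan2(pts[i, 2], pts[i, 1]), 0), obj,
               method = "Nelder-Mead",
               control = list(reltol = 1e-12, maxit = 5000))
    expect_lt(abs(d_pkg[i] - o$value), 1)
  }
})
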