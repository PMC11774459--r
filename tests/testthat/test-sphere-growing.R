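test_that("opposing force vanishes on constants, is unit-bounded, and points into bright disks", {
  cfg <- growth_config()
  const <- volume(array(100, dim = c(15, 15, 15)), spacing = rep(0.7, 3))
  u <- opposing_force_field(const, cfg)
  expect_equal(max(abs(u$vectors)), 0)

  set.seed(21)
  noisy <- volume(array(runif(15^3, -1000, 400), dim = c(15, 15, 15)),
                  spacing = rep(0.7, 3))
  u <- opposing_force_field(noisy, cfg)$vectors
  mag <- sqrt(u[, , , 1]^2 + u[, , , 2]^2 + u[, , , 3]^2)
  expect_lte(max(mag), 1 + 1e-9)

  # bright ball: at boundary voxels the force has positive inward component
  ball <- make_ball_volume(6, c(12, 12, 12))
  u <- opposing_force_field(ball, mask_growth_config())$vectors
  g <- index_grid(dim(ball$voxels))
  r <- sqrt(rowSums(sweep(g, 2, c(12, 12, 12))^2))
  shell <- which(abs(r - 6) < 0.7 & r > 0)
  inward <- -sweep(g[shell, ], 2, c(12, 12, 12)) / r[shell]
  dots <- rowSums(cbind(u[, , , 1][shell], u[, , , 2][shell],
                        u[, , , 3][shell]) * inward)
  expect_gt(mean(dots > 0), 0.95)
  expect_gt(mean(dots), 0.3)

  aniso <- volume(array(0, dim = c(5, 5, 5)), spacing = c(1, 1, 2))
  expect_error(opposing_force_field(aniso, cfg), "isotropic")
})

test_that("zero-force growth follows the closed-form recurrence deterministically", {
  cfg <- mask_growth_config(n_iter = 30L)
  const <- volume(array(0.5, dim = c(41, 41, 41)), spacing = rep(1, 3))
  traj <- grow_sphere(const, c(20, 20, 20), cfg)
  n <- traj$states$iteration
  expect_equal(traj$states$radius, cfg$r0 + n * cfg$f_int, tolerance = 1e-9)
  expect_identical(traj$states$cx, rep(20, 31))   # bit-stable centre
  expect_identical(traj$states$cy, rep(20, 31))
  expect_identical(traj$states$cz, rep(20, 31))
  expect_true(all(diff(traj$states$radius) > 0)) # monotone in vessel-free space

  traj2 <- grow_sphere(const, c(20, 20, 20), cfg)
  expect_identical(traj$states, traj2$states)
})

test_that("growth on solid balls matches the distance-transform oracle", {
  set.seed(22)
  cfg <- mask_growth_config(n_iter = 150L)
  for (k in 1:5) {
    R <- runif(1, 3, 8)
    cen <- 12 + runif(3, -0.5, 0.5)
    ball <- make_ball_volume(R, cen)
    seed <- cen + runif(3, -1, 1) * 2 / sqrt(3)
    traj <- grow_sphere(ball, seed, cfg)
    oracle <- edt_deep_center(ball$voxels)
    expect_false(traj$diverged)
    expect_lt(sqrt(sum((traj$final_center - oracle$center)^2)), 0.5)
    expect_lt(abs(traj$final_radius - R), 1)
  }
})

test_that("growth is consistent under lossless 90-degree rotation", {
  set.seed(23)
  ball <- make_ball_volume(5.3, c(12.2, 11.7, 12.4))
  cfg <- mask_growth_config(n_iter = 100L)
  t1 <- grow_sphere(ball, c(11, 12, 13), cfg)
  # rotate 90 degrees about z: (x, y) -> (ny - 1 - y, x)
  rot <- ball
  rot$voxels <- aperm(ball$voxels, c(2, 1, 3))[25:1, , ]
  seed_rot <- c(25 - 1 - 12, 11, 13)
  t2 <- grow_sphere(rot, seed_rot, cfg)
  mapped <- c(25 - 1 - t1$final_center[2], t1$final_center[1],
              t1$final_center[3])
  expect_lt(sqrt(sum((t2$final_center - mapped)^2)), 0.25)
})

test_that("divergence detection: radius cap, drift out of patch, stable tube", {
  cfg <- mask_growth_config(n_iter = 200L, radius_cap = 10, drift_cap = 8)
  const <- volume(array(0.5, dim = c(61, 61, 61)), spacing = rep(1, 3))
  traj <- grow_sphere(const, c(30, 30, 30), cfg)
  expect_true(traj$diverged)
  expect_equal(traj$divergence_reason, "radius_cap")
  # first iteration past the cap: closed form ceil((cap - r0)/f_int)
  expect_equal(nrow(traj$states) - 1L,
               as.integer(ceiling((cfg$radius_cap - cfg$r0) / cfg$f_int)))
  dd <- detect_divergence(traj, const, cfg)
  expect_true(dd$diverged)
  expect_equal(dd$reason, "radius_cap")

  # intensity ramp brightest at a face pulls the centre out of the patch
  d <- c(21L, 21L, 21L)
  ramp <- volume(array(rep((0:20) / 20, times = 21 * 21), dim = d))
  cfg2 <- mask_growth_config(n_iter = 200L, drift_cap = 50)
  traj2 <- grow_sphere(ramp, c(2, 10, 10), cfg2)
  expect_true(traj2$diverged)
  expect_equal(traj2$divergence_reason, "left_patch")

  # confined stable growth inside a wide tube does not diverge
  tube <- make_tube_volume(6, dimn = 31, intensity = 1, background = 0)
  traj3 <- grow_sphere(tube, c(15, 15, 15), mask_growth_config(n_iter = 60L))
  expect_false(traj3$diverged)
  expect_equal(detect_divergence(traj3, tube,
                                 mask_growth_config())$reason, "none")
})

test_that("refine_landmark converges on a clean junction with substrate 'image'", {
  ph <- make_vessel_phantom(yjunction_phantom_spec(), spacing = 1)
  lm <- ph$landmarks
  lm$type <- "type1"
  cfg <- growth_config(n_iter = 60L, patch_size_mm = 40)
  out <- refine_landmark(ph$volume, lm, cfg)
  expect_equal(out$substrate, "image")
  expect_equal(out$flagged, 0L)

  # oracle: deepest point (distance-transform centre) of the generating
  # vessel mask within 8 mm of the junction
  mask <- ph$volume
  d <- dim(mask$voxels)
  mask$voxels <- array(as.numeric(ph$volume$voxels > -350), dim = d)
  jc <- world_to_voxel(mask, c(lm$x_mm, lm$y_mm, lm$z_mm))
  g <- index_grid(d)
  keep <- mask
  keep$voxels <- array(0, dim = d)
  near <- g[rowSums(sweep(g, 2, jc)^2) <= 8^2, , drop = FALSE] + 1
  keep$voxels[near] <- mask$voxels[near]
  oracle_mm <- voxel_to_world(mask, edt_deep_center(keep$voxels)$center)
  err_mm <- sqrt(sum((c(out$x_mm, out$y_mm, out$z_mm) - oracle_mm)^2))
  expect_lt(err_mm, 1.0)

  lm2 <- lm
  lm2$type <- "type2"
  expect_error(refine_landmark(ph$volume, lm2, cfg), "type-1")
})

test_that("refinement falls back down the substrate ladder and flags failures", {
  # uniform bright block: no gradient, image growth diverges; vesselness
  # is zero so the automatic mask is empty; a manual ball mask rescues it
  d <- c(61L, 61L, 61L)
  v <- volume(array(240, dim = d), spacing = rep(1, 3))
  lm <- landmark_frame(id = "a", x_mm = 30, y_mm = 30, z_mm = 30,
                       type = "type1")
  mball <- make_ball_volume(5, c(30, 30, 30), dimn = 61)
  cfg <- growth_config(n_iter = 60L, patch_size_mm = 36, radius_cap = 8)
  out <- refine_landmark(v, lm, cfg, manual_mask = mball)
  expect_equal(out$substrate, "manual_mask")
  expect_lt(sqrt(sum((c(out$x_mm, out$y_mm, out$z_mm) - c(30, 30, 30))^2)), 1)

  # without the manual mask every substrate fails -> flagged, unmoved
  out2 <- refine_landmark(v, lm, cfg)
  expect_equal(out2$substrate, "none")
  expect_equal(out2$flagged, 1L)
  expect_equal(c(out2$x_mm, out2$y_mm, out2$z_mm), c(30, 30, 30))

  # low-contrast tube on a bright background: image growth escapes but the
  # vesselness mask still captures the tube -> substrate auto_mask
  tube <- make_tube_volume(3, dimn = 41, intensity = 240, background = 190)
  lm3 <- landmark_frame(id = "t", x_mm = 20, y_mm = 20, z_mm = 20,
                        type = "type1")
  out3 <- refine_landmark(tube, lm3, growth_config(n_iter = 60L,
                                                   patch_size_mm = 26,
                                                   radius_cap = 8))
  expect_equal(out3$substrate, "auto_mask")
})
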