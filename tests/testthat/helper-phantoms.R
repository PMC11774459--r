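# Shared fixtures: analytic phantoms and independent oracles.
# Everything here is deliberately simple, loop-based code so it stays
# independent of the vectorised implementation paths it checks.

# Binary solid ball (values 0/1) on a unit grid; center in 0-based
# continuous voxel coordinates.
make_ball_volume <- function(radius, center, dimn = 25L) {
  g <- index_grid(c(dimn, dimn, dimn))
  d <- sqrt((g[, 1] - center[1])^2 + (g[, 2] - center[2])^2 +
              (g[, 3] - center[3])^2)
  volume(array(as.numeric(d <= radius), dim = rep(dimn, 3L)))
}
# index_grid is internal; reimplement locally to stay independent
index_grid <- function(d) {
  as.matrix(expand.grid(x = 0:(d[1] - 1), y = 0:(d[2] - 1),
                        z = 0:(d[3] - 1)))
}

# Brute-force Euclidean distance transform oracle: for every foreground
# voxel, the distance to the nearest background voxel (chunked to bound
# memory). Returns the sub-voxel "deep centre": the centroid of voxels
# whose EDT is within 1 voxel of the maximum.
edt_deep_center <- function(mask_arr) {
  d <- dim(mask_arr)
  g <- index_grid(d)
  fg <- which(mask_arr > 0)
  bg <- which(mask_arr == 0)
  stopifnot(length(fg) > 0, length(bg) > 0)
  bgc <- g[bg, , drop = FALSE]
  edt <- numeric(length(fg))
  chunk <- 400L
  for (s in seq(1L, length(fg), by = chunk)) {
    e <- min(s + chunk - 1L, length(fg))
    fc <- g[fg[s:e], , drop = FALSE]
    d2 <- outer(rowSums(fc^2), rep(1, nrow(bgc))) +
      outer(rep(1, nrow(fc)), rowSums(bgc^2)) - 2 * fc %*% t(bgc)
    edt[s:e] <- sqrt(pmax(apply(d2, 1, min), 0))
  }
  top <- fg[edt >= max(edt) - 1]
  list(center = colMeans(g[top, , drop = FALSE]),
       max_edt = max(edt))
}

# Solid axis-aligned tube along `axis` through the volume centre.
make_tube_volume <- function(radius_mm, dimn = 41L, spacing = 1,
                             axis = 3L, intensity = 300, background = -1000) {
  g <- index_grid(rep(dimn, 3L)) * spacing
  cen <- rep((dimn - 1) / 2 * spacing, 3)
  plane <- setdiff(1:3, axis)
  d <- sqrt((g[, plane[1]] - cen[plane[1]])^2 +
              (g[, plane[2]] - cen[plane[2]])^2)
  vals <- ifelse(d <= radius_mm, intensity, background)
  volume(array(vals, dim = rep(dimn, 3L)), spacing = rep(spacing, 3))
}

# Solid plate of given half-thickness normal to `axis`.
make_plate_volume <- function(half_thickness_mm, dimn = 41L, spacing = 1,
                              axis = 3L, intensity = 300,
                              background = -1000) {
  g <- index_grid(rep(dimn, 3L)) * spacing
  cen <- (dimn - 1) / 2 * spacing
  vals <- ifelse(abs(g[, axis] - cen) <= half_thickness_mm, intensity,
                 background)
  volume(array(vals, dim = rep(dimn, 3L)), spacing = rep(spacing, 3))
}

# Random landmark table for I/O round trips.
random_landmarks <- function(n, seed = 1) {
  set.seed(seed)
  landmark_frame(
    id = sprintf("L%04d", seq_len(n)),
    case = sample(sprintf("case%02d", 1:5), n, replace = TRUE),
    image = sample(1:2, n, replace = TRUE),
    x_mm = stats::rnorm(n, 0, 100), y_mm = stats::rnorm(n, 0, 100),
    z_mm = stats::rnorm(n, 0, 100),
    type = sample(c("type1", "type2", "unrefined"), n, replace = TRUE),
    flagged = sample(0:1, n, replace = TRUE),
    substrate = sample(c("image", "auto_mask", "manual_mask", "none"), n,
                       replace = TRUE))
}

# Growth config used for binary-mask substrates in tests.
mask_growth_config <- function(...) {
  growth_config(intensity_window = NULL, ...)
}

# Independent Rodrigues rotation (for constructing test geometries).
rotation_matrix_for_test <- function(axis, angle_deg) {
  k <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  kx <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
  diag(3) + sin(th) * kx + (1 - cos(th)) * (kx %*% kx)
}
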