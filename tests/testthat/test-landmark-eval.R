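test_that("diameter-ratio classification has an inclusive 2.5 boundary", {
  expect_equal(classify_bifurcation(5.0, 2.0), "type2") # exactly 2.5
  expect_equal(classify_bifurcation(3.0, 2.0), "type1")
  expect_equal(classify_bifurcation(10.0, 1.0), "type2")
  expect_error(classify_bifurcation(3, 0), "d_large >= d_small > 0")
  expect_error(classify_bifurcation(2, 3), "d_large >= d_small > 0")
})

test_that("type-2 points land on the large-vessel surface", {
  # analytic cylinder of radius 5 mm around the y-axis, sampled at 1 mm
  d <- c(31L, 31L, 31L)
  cyl <- volume(array(0, dim = d), origin = c(-15, -15, -15))
  w <- voxel_to_world(cyl, index_grid(d))
  cyl$voxels <- array(as.numeric(sqrt(w[, 1]^2 + w[, 3]^2) <= 5), dim = d)

  # centreline along +x entering the cylinder: crossing at x = -5
  line <- cbind(seq(-14, 0, by = 1), 0, 0)
  hit <- type2_point(line, cyl)
  expect_lt(abs(hit[1] + 5), 0.75) # within voxel tolerance of the surface
  expect_lt(max(abs(hit[2:3])), 1e-9)

  # invariance to resampling density of the same polyline
  line2 <- cbind(seq(-14, 0, by = 0.05), 0, 0)
  hit2 <- type2_point(line2, cyl)
  expect_lt(sqrt(sum((hit - hit2)^2)), 0.01)

  # a polyline starting exactly on the interpolated boundary returns it
  start <- type2_point(rbind(hit, c(0, 0, 0)), cyl)
  expect_lt(sqrt(sum((start - hit)^2)), 0.01)

  outside <- cbind(seq(-14, -10, by = 1), 12, 0)
  expect_error(type2_point(outside, cyl), "never crosses")
})

test_that("DVF projection matches closed-form displacement fields", {
  lms <- landmark_frame(id = c("a", "b", "c"), x_mm = c(2, 7, 11),
                        y_mm = c(3, 8, 2), z_mm = c(4, 6, 9))
  d <- c(16L, 16L, 16L)
  zero <- vector_field(array(0, dim = c(d, 3)))
  pz <- project_landmarks_through_dvf(lms, zero)
  expect_equal(pz[, c("x_mm", "y_mm", "z_mm")], lms[, c("x_mm", "y_mm", "z_mm")])
  expect_false(any(pz$out_of_grid))

  const <- vector_field(outer(array(1, dim = d), c(3, -2, 1)))
  pc <- project_landmarks_through_dvf(lms, const)
  expect_equal(pc$x_mm, lms$x_mm + 3)
  expect_equal(pc$y_mm, lms$y_mm - 2)
  expect_equal(pc$z_mm, lms$z_mm + 1)

  # linear field d(p) = (0.1 * y, 0, 0) is trilinear-exact
  g <- index_grid(d)
  lin <- array(0, dim = c(d, 3))
  lin[, , , 1] <- array(0.1 * g[, 2], dim = d)
  pl <- project_landmarks_through_dvf(lms, vector_field(lin))
  expect_equal(pl$x_mm, lms$x_mm + 0.1 * lms$y_mm, tolerance = 1e-6)

  # out-of-grid landmarks are flagged, not moved
  far <- landmark_frame(id = "far", x_mm = 100, y_mm = 0, z_mm = 0)
  pf <- project_landmarks_through_dvf(far, const)
  expect_true(pf$out_of_grid)
  expect_equal(pf$x_mm, 100)
})

test_that("landmark errors equal brute-force distances and respect rigid motion", {
  a <- random_landmarks(100, seed = 41)
  b <- random_landmarks(100, seed = 42)
  d <- landmark_errors(a, b)
  # independent elementwise oracle
  oracle <- numeric(100)
  for (i in 1:100) {
    j <- which(b$id == a$id[i])
    oracle[i] <- sqrt((a$x_mm[i] - b$x_mm[j])^2 + (a$y_mm[i] - b$y_mm[j])^2 +
                        (a$z_mm[i] - b$z_mm[j])^2)
  }
  expect_lt(max(abs(d - oracle)), 1e-12)
  expect_equal(unname(landmark_errors(b, a)[a$id]), unname(d)) # symmetry

  expect_equal(unname(landmark_errors(a, a)), rep(0, 100))
  one <- landmark_frame(id = "p", x_mm = 0, y_mm = 0, z_mm = 0)
  two <- landmark_frame(id = "p", x_mm = 3, y_mm = 4, z_mm = 0)
  expect_equal(unname(landmark_errors(one, two)), 5)

  # common rigid motion leaves the distances unchanged
  R <- rotation_matrix_for_test(c(2, -1, 3), 29)
  shift <- c(10, -4, 6)
  rot <- function(df) {
    p <- as.matrix(df[, c("x_mm", "y_mm", "z_mm")]) %*% t(R)
    df$x_mm <- p[, 1] + shift[1]; df$y_mm <- p[, 2] + shift[2]
    df$z_mm <- p[, 3] + shift[3]
    df
  }
  expect_lt(max(abs(landmark_errors(rot(a), rot(b)) - d)), 1e-9)

  bad <- b
  bad$id[1] <- "nope"
  expect_error(landmark_errors(a, bad), "ids do not match")
})

test_that("error summaries apply the hard outlier cutoff as stated", {
  s <- summarize_errors(c(1, 1, 1, 10), cutoff = 5)
  expect_equal(s$n_excluded, 1L)
  expect_equal(s$mean, 1)
  expect_equal(s$std, 0)
  expect_equal(s$n_total, 4L)

  s2 <- summarize_errors(c(0.4, 1.2, 2.2))
  expect_equal(s2$n_excluded, 0L)
  expect_equal(s2$mean, mean(c(0.4, 1.2, 2.2)))
  expect_equal(s2$std, stats::sd(c(0.4, 1.2, 2.2)))

  sInf <- summarize_errors(c(1, 1, 1, 10), cutoff = Inf)
  sNone <- summarize_errors(c(1, 1, 1, 10))
  expect_equal(sInf$mean, sNone$mean)
  expect_equal(sInf$n_excluded, sNone$n_excluded)

  expect_error(summarize_errors(numeric(0)), "no distances")
  expect_error(summarize_errors(c(7, 8), cutoff = 5), "all distances excluded")
})

test_that("paired t-test matches the closed form and a quadrature oracle", {
  # worked example: differences 1..5 -> t = 3 / (1.5811 / sqrt(5)) = 4.2426
  a <- c(1, 2, 3, 4, 5)
  b <- rep(0, 5)
  r <- paired_t_test(a, b)
  expect_equal(r$t_statistic, 3 / (stats::sd(a) / sqrt(5)), tolerance = 1e-12)
  expect_equal(r$t_statistic, 4.2426, tolerance = 1e-4)
  expect_equal(r$degrees_of_freedom, 4L)
  # p oracle: numerically integrated t density with 4 df
  dens <- function(x) (gamma(2.5) / (sqrt(4 * pi) * gamma(2))) *
    (1 + x^2 / 4)^(-2.5)
  p_oracle <- 2 * stats::integrate(dens, abs(r$t_statistic), Inf,
                                   rel.tol = 1e-12)$value
  expect_equal(r$p_value, p_oracle, tolerance = 1e-6)
  # cross-check against the reference implementation
  tt <- stats::t.test(a, b, paired = TRUE)
  expect_equal(r$t_statistic, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(r$p_value, tt$p.value, tolerance = 1e-12)

  # zero mean difference
  z <- paired_t_test(c(1, 0, 1, 0), c(0, 1, 0, 1))
  expect_equal(z$t_statistic, 0)
  expect_equal(z$p_value, 1)

  # antisymmetry
  set.seed(44)
  x <- rnorm(20); y <- rnorm(20)
  expect_equal(paired_t_test(x, y)$t_statistic,
               -paired_t_test(y, x)$t_statistic)
  expect_equal(paired_t_test(x, y)$p_value, paired_t_test(y, x)$p_value)

  expect_error(paired_t_test(c(1, 2), c(0, 1)), "zero variance")
  expect_error(paired_t_test(1, 0), "at least 2")
})

test_that("evaluate_dir computes TREs through a DVF", {
  ph <- make_vessel_phantom(yjunction_phantom_spec(), spacing = 1)
  lms1 <- ph$landmarks
  tr <- sample_phantom_transform(seed = 12,
                                 pivot = c(lms1$x_mm, lms1$y_mm, lms1$z_mm))
  lms2 <- lms1
  p2 <- map_point_forward(as.matrix(lms1[, c("x_mm", "y_mm", "z_mm")]), tr)
  lms2$x_mm <- p2[, 1]; lms2$y_mm <- p2[, 2]; lms2$z_mm <- p2[, 3]

  # ground-truth DVF sampled from the exact forward map on the image grid
  d <- dim(ph$volume$voxels)
  w <- voxel_to_world(ph$volume, index_grid(d))
  disp <- map_point_forward(w, tr) - w
  dvf <- vector_field(array(disp, dim = c(d, 3)), spacing = ph$volume$spacing,
                      origin = ph$volume$origin)
  s <- evaluate_dir(lms1, lms2, dvf)
  expect_lt(s$mean, 0.2) # only interpolation error remains

  # zero DVF on a pair with a known 10 mm offset
  lms10 <- lms1
  lms10$x_mm <- lms10$x_mm + 10
  z <- evaluate_dir(lms1, lms10, vector_field(array(0, dim = c(d, 3)),
                                              spacing = ph$volume$spacing,
                                              origin = ph$volume$origin))
  expect_equal(z$mean, 10, tolerance = 1e-9)
})
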