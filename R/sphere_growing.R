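#' Configuration for sphere-growing bifurcation refinement
#'
#' Parameters of the iterative sphere-growing refinement. A sphere of
#' initial radius `r0` voxels is inflated at the seed landmark; each
#' iteration the radius grows by a constant internal force `f_int`
#' opposed by the image-gradient force sampled on a shell around the
#' sphere surface, and the centre moves along the mean gradient force,
#' so the sphere settles into the widest point of the vessel junction.
#'
#' Units are voxels of the isotropically resampled patch throughout.
#'
#' @param lambda1 Centre-update gain (default 0.2).
#' @param lambda2 Radius-update gain on the opposing force (default 0.3).
#' @param f_int Constant outward internal force, voxels per iteration
#'   (default 0.18). Must be smaller than the maximum braking force
#'   `lambda2` (the opposing force has unit-bounded magnitude), or the
#'   gradient force can never arrest growth at the vessel wall.
#' @param n_iter Number of iterations (default 30).
#' @param r0 Initial radius in voxels (default 0.5).
#' @param shell_half_width Half-width of the support shell around the
#'   sphere surface, voxels (default 1.5).
#' @param grad_epsilon Regulariser added to the gradient norm before
#'   normalisation, in units of window-normalised intensity per voxel
#'   (default 0.01); suppresses spurious unit forces in flat regions.
#' @param intensity_window HU window `c(lo, hi)` used to normalise
#'   intensities to `[0, 1]` (default `c(-160, 240)`); `NULL` means the
#'   input is already a 0/1 mask and is only clamped.
#' @param radius_cap Radius (voxels) beyond which growth is declared
#'   divergent (default 25).
#' @param drift_cap Centre drift from the seed (voxels) beyond which
#'   growth is declared divergent (default 15).
#' @param patch_size_mm Side of the cubic patch extracted around a
#'   landmark before refinement (default 100 mm).
#' @param target_spacing_mm Isotropic resampling target (default 0.7 mm).
#' @return A `growth_config` list.
#' @export
growth_config <- function(lambda1 = 0.2, lambda2 = 0.3, f_int = 0.18,
                          n_iter = 30L, r0 = 0.5, shell_half_width = 1.5,
                          grad_epsilon = 0.01,
                          intensity_window = c(-160, 240),
                          radius_cap = 25, drift_cap = 15,
                          patch_size_mm = 100, target_spacing_mm = 0.7) {
  stopifnot(lambda1 > 0, lambda2 > 0, f_int > 0, n_iter >= 1, r0 > 0,
            shell_half_width > 0, grad_epsilon > 0, radius_cap > 0,
            drift_cap > 0, patch_size_mm > 0, target_spacing_mm > 0)
  if (!is.null(intensity_window)) {
    stopifnot(length(intensity_window) == 2L,
              intensity_window[1] < intensity_window[2])
  }
  structure(list(lambda1 = lambda1, lambda2 = lambda2, f_int = f_int,
                 n_iter = as.integer(n_iter), r0 = r0,
                 shell_half_width = shell_half_width,
                 grad_epsilon = grad_epsilon,
                 intensity_window = intensity_window,
                 radius_cap = radius_cap, drift_cap = drift_cap,
                 patch_size_mm = patch_size_mm,
                 target_spacing_mm = target_spacing_mm),
            class = "growth_config")
}

#' Gradient-based opposing force field
#'
#' Computes the per-voxel force `u(X) = (1 - I_norm(X)) * g(X) / (||g(X)|| +
#' eps)` on an isotropic patch, where `I_norm` is the window-normalised
#' intensity in `[0, 1]` and `g` is the sigma = 1 voxel Gaussian-smoothed
#' gradient. The force vanishes inside bright vessels (`I_norm -> 1`),
#' points inward at vessel borders, and has magnitude at most 1
#' everywhere; it is what stops the growing sphere at the vessel wall.
#'
#' @param patch An isotropic, HU-windowed [volume()] (or a 0/1 mask when
#'   `config$intensity_window` is `NULL`).
#' @param config A [growth_config()].
#' @return A [vector_field()] of unit-bounded forces (per-voxel units).
#' @export
opposing_force_field <- function(patch, config = growth_config()) {
  if (!is_volume(patch)) stop("'patch' must be a volume")
  if (!is_isotropic(patch))
    stop("'patch' must be isotropically resampled")
  w <- config$intensity_window
  inorm <- if (is.null(w)) {
    pmin(pmax(patch$voxels, 0), 1)
  } else {
    (pmin(pmax(patch$voxels, w[1]), w[2]) - w[1]) / (w[2] - w[1])
  }
  inorm <- array(inorm, dim = dim(patch$voxels))
  sm <- smooth_gaussian(inorm, 1)
  d <- dim(sm)
  g <- array(0, dim = c(d, 3))
  for (ax in 1:3) g[, , , ax] <- central_diff(sm, ax) # per-voxel units
  gnorm <- sqrt(g[, , , 1]^2 + g[, , , 2]^2 + g[, , , 3]^2)
  # the (1 - I) factor uses the smoothed intensity so the braking force
  # is continuous across the vessel wall (an exact binary wall would
  # otherwise give zero force on its inside voxels)
  scale <- (1 - sm) / (gnorm + config$grad_epsilon)
  for (ax in 1:3) g[, , , ax] <- g[, , , ax] * scale
  vector_field(g, spacing = patch$spacing, origin = patch$origin,
               orientation = patch$orientation, units = "force")
}

# Deterministic spherical Fibonacci lattice of m unit directions.
fibonacci_directions <- function(m) {
  i <- seq_len(m) - 0.5
  z <- 1 - 2 * i / m
  s <- sqrt(pmax(1 - z^2, 0))
  theta <- pi * (1 + sqrt(5)) * i
  cbind(s * cos(theta), s * sin(theta), z)
}

# Shell sample points and outward unit directions for radius r centred
# at the origin: three sub-shells at r - h, r, r + h (h = shell half
# width), each with >= max(64, 4*pi*rad^2) Fibonacci directions.
shell_samples <- function(r, half_width) {
  radii <- unique(pmax(r + c(-half_width, 0, half_width), 0.25))
  dirs <- NULL
  rads <- NULL
  for (rad in radii) {
    m <- max(64L, as.integer(ceiling(4 * pi * rad^2)))
    dd <- fibonacci_directions(m)
    dirs <- rbind(dirs, dd)
    rads <- c(rads, rep(rad, m))
  }
  list(dirs = dirs, radii = rads)
}

divergence_state <- function(center, radius, seed, d, config) {
  if (radius > config$radius_cap) return("radius_cap")
  if (sqrt(sum((center - seed)^2)) > config$drift_cap) return("center_drift")
  if (any(center < 0) || any(center > d - 1)) return("left_patch")
  "none"
}

#' Grow a sphere to the widest point of a vessel junction
#'
#' Runs the iterative sphere-growing recurrence on an isotropic,
#' intensity-windowed patch, starting from a seed point (continuous
#' 0-based voxel coordinates). Each iteration updates
#' `c <- c + lambda1 * mean(u)` and
#' `r <- r + f_int + lambda2 * mean(dot(dir, u))`,
#' with both means taken over a shell of half-width
#' `config$shell_half_width` around the sphere surface; forces are
#' trilinearly interpolated at the continuous shell points. The centre
#' converges to the locally widest point of the vessel (the bifurcation)
#' and the radius to the local vessel radius. The loop is fully
#' deterministic.
#'
#' @param patch An isotropic [volume()], windowed per the config.
#' @param seed Length-3 continuous 0-based voxel coordinates.
#' @param config A [growth_config()].
#' @param force Optional precomputed [opposing_force_field()] for
#'   `patch` (computed internally when `NULL`).
#' @return A `sphere_trajectory`: list with `states` (data.frame of
#'   iteration, cx, cy, cz, radius), `diverged`, `divergence_reason`
#'   (`"none"`, `"radius_cap"`, `"center_drift"`, `"left_patch"`),
#'   `final_center`, `final_radius`.
#' @export
grow_sphere <- function(patch, seed, config = growth_config(), force = NULL) {
  if (!is_volume(patch)) stop("'patch' must be a volume")
  if (!is_isotropic(patch)) stop("'patch' must be isotropic")
  d <- dim(patch$voxels)
  seed <- as.numeric(seed)
  if (length(seed) != 3L || any(!is.finite(seed)))
    stop("'seed' must be a finite 3-vector of voxel coordinates")
  if (any(seed < 0) || any(seed > d - 1))
    stop("seed lies outside the patch")
  if (is.null(force)) force <- opposing_force_field(patch, config)

  cen <- seed
  r <- config$r0
  n_iter <- config$n_iter
  states <- matrix(NA_real_, n_iter + 1L, 4L)
  states[1L, ] <- c(cen, r)
  diverged <- FALSE
  reason <- "none"
  n_done <- 0L
  for (n in seq_len(n_iter)) {
    sh <- shell_samples(r, config$shell_half_width)
    pts <- sweep(sh$dirs * sh$radii, 2, cen, "+")
    ux <- interp_trilinear(force$vectors[, , , 1], pts)
    inb <- !is.na(ux)
    if (!any(inb)) {
      diverged <- TRUE
      reason <- "left_patch"
      break
    }
    uy <- interp_trilinear(force$vectors[, , , 2], pts[inb, , drop = FALSE])
    uz <- interp_trilinear(force$vectors[, , , 3], pts[inb, , drop = FALSE])
    ux <- ux[inb]
    dirs <- sh$dirs[inb, , drop = FALSE]
    cen <- cen + config$lambda1 * c(mean(ux), mean(uy), mean(uz))
    r <- r + config$f_int +
      config$lambda2 * mean(dirs[, 1] * ux + dirs[, 2] * uy + dirs[, 3] * uz)
    n_done <- n
    states[n + 1L, ] <- c(cen, r)
    dv <- divergence_state(cen, r, seed, d, config)
    if (dv != "none") {
      diverged <- TRUE
      reason <- dv
      break
    }
  }
  states <- states[seq_len(n_done + 1L), , drop = FALSE]
  st <- data.frame(iteration = seq_len(nrow(states)) - 1L,
                   cx = states[, 1], cy = states[, 2], cz = states[, 3],
                   radius = states[, 4])
  structure(list(states = st, diverged = diverged,
                 divergence_reason = reason,
                 final_center = states[nrow(states), 1:3],
                 final_radius = states[nrow(states), 4]),
            class = "sphere_trajectory")
}

#' @export
print.sphere_trajectory <- function(x, ...) {
  cat(sprintf(
    "<sphere_trajectory> %d iterations, final r = %.2f vox at (%.2f, %.2f, %.2f)%s\n",
    nrow(x$states) - 1L, x$final_radius,
    x$final_center[1], x$final_center[2], x$final_center[3],
    if (x$diverged) sprintf(" [diverged: %s]", x$divergence_reason) else ""))
  invisible(x)
}

#' Re-check a trajectory for divergence
#'
#' Applies the divergence rules to a recorded trajectory: radius beyond
#' `config$radius_cap`, cumulative centre drift from the seed beyond
#' `config$drift_cap`, or the centre leaving the patch.
#'
#' @param traj A `sphere_trajectory` from [grow_sphere()].
#' @param patch The patch the trajectory was grown on.
#' @param config A [growth_config()].
#' @return List with `diverged` (logical) and `reason`.
#' @export
detect_divergence <- function(traj, patch, config = growth_config()) {
  if (!inherits(traj, "sphere_trajectory")) stop("'traj' must be a trajectory")
  st <- traj$states
  if (nrow(st) == 0L) stop("trajectory is empty")
  d <- dim(patch$voxels)
  seed <- as.numeric(st[1L, c("cx", "cy", "cz")])
  for (i in seq_len(nrow(st))) {
    dv <- divergence_state(as.numeric(st[i, c("cx", "cy", "cz")]),
                           st$radius[i], seed, d, config)
    if (dv != "none") return(list(diverged = TRUE, reason = dv))
  }
  if (traj$diverged) return(list(diverged = TRUE,
                                 reason = traj$divergence_reason))
  list(diverged = FALSE, reason = "none")
}

#' Refine a type-1 bifurcation landmark by sphere growing
#'
#' Extracts a cubic patch (default 100 mm) around the landmark,
#' resamples it to isotropic resolution (default 0.7 mm), windows it to
#' (-160, 240) HU, and grows a sphere from the landmark. If growth
#' diverges on the image, the algorithm is re-run on an automatically
#' generated vessel mask (multiscale vesselness + region growing); if
#' that also diverges and a user-supplied (manual) vessel mask is given,
#' it is tried last. The substrate ladder is image, then automatic
#' mask, then manual mask. If every substrate diverges the landmark is
#' returned unchanged with `flagged = 1` and `substrate = "none"`.
#'
#' @param vol The full [volume()] (HU).
#' @param lm A one-row landmark data frame (see [landmark_frame()]);
#'   must have `type == "type1"`.
#' @param config A [growth_config()].
#' @param manual_mask Optional binary [volume()] (full-volume geometry)
#'   used as the last-resort substrate.
#' @param vconfig A [vesselness_config()] for the automatic-mask fallback.
#' @param mask_threshold Region-growing threshold on the normalised
#'   vesselness (default 0.05).
#' @return The landmark row with refined world-mm position, `substrate`
#'   in `c("image", "auto_mask", "manual_mask", "none")` and `flagged`
#'   updated; the winning trajectory is attached as attribute
#'   `"trajectory"`.
#' @export
refine_landmark <- function(vol, lm, config = growth_config(),
                            manual_mask = NULL,
                            vconfig = vesselness_config(),
                            mask_threshold = 0.05) {
  if (!is.data.frame(lm) || nrow(lm) != 1L)
    stop("'lm' must be a one-row landmark data frame")
  if (!identical(lm$type, "type1"))
    stop("only type-1 landmarks are sphere-grown; type-2 points are placed geometrically")
  p <- c(lm$x_mm, lm$y_mm, lm$z_mm)

  patch <- extract_patch(vol, p, config$patch_size_mm, fill = -1000)
  patch <- resample_isotropic(patch, config$target_spacing_mm)
  img <- hu_window(patch, config$intensity_window[1], config$intensity_window[2])
  seed <- world_to_voxel(img, p)

  finish <- function(traj, substrate) {
    out <- lm
    w <- voxel_to_world(img, traj$final_center)
    out$x_mm <- w[1]; out$y_mm <- w[2]; out$z_mm <- w[3]
    out$substrate <- substrate
    attr(out, "trajectory") <- traj
    out
  }

  traj <- grow_sphere(img, seed, config)
  if (!traj$diverged) return(finish(traj, "image"))

  mask_cfg <- config
  mask_cfg$intensity_window <- NULL
  seed_vox <- as.integer(round(seed)) + 1L # 1-based for region_grow
  amask <- tryCatch(
    auto_vessel_mask(img, seed_vox, vconfig, threshold = mask_threshold),
    error = function(e) NULL)
  if (!is.null(amask) && sum(amask$voxels) > 0) {
    traj <- grow_sphere(amask, seed, mask_cfg)
    if (!traj$diverged) return(finish(traj, "auto_mask"))
  }

  if (!is.null(manual_mask)) {
    mpatch <- extract_patch(manual_mask, p, config$patch_size_mm, fill = 0,
                            method = "nearest")
    mpatch <- resample_isotropic(mpatch, config$target_spacing_mm,
                                 method = "nearest")
    if (sum(mpatch$voxels) > 0) {
      traj <- grow_sphere(mpatch, world_to_voxel(mpatch, p), mask_cfg)
      if (!traj$diverged) return(finish(traj, "manual_mask"))
    }
  }

  out <- lm
  out$flagged <- 1L
  out$substrate <- "none"
  attr(out, "trajectory") <- traj
  out
}
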