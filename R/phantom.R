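#' Specification of a synthetic vessel phantom
#'
#' Describes a synthetic contrast-enhanced vessel scene: bright tube
#' segments on a dark (air-like) background, with known junction
#' (bifurcation) points. Used to exercise the refinement and
#' evaluation machinery with exact ground truth in place of real CECT
#' patches.
#'
#' @param segments Data frame with columns `x1, y1, z1, x2, y2, z2`
#'   (segment endpoints, world mm), `radius` (mm, > 0) and `intensity`
#'   (HU).
#' @param junctions Data frame with columns `x, y, z` (world mm),
#'   `d_large`, `d_small` (branch diameters in mm). Each junction point
#'   must lie on the axis of at least two segments (tolerance 1e-6 mm).
#' @param background Background intensity, HU (default -1000).
#' @param noise_sigma Additive Gaussian noise sigma, HU (default 0).
#' @param margin_mm Padding added around the segment bounding box when
#'   rasterising (default 8 mm).
#' @return A `vessel_phantom_spec` list.
#' @export
vessel_phantom_spec <- function(segments, junctions = NULL,
                                background = -1000, noise_sigma = 0,
                                margin_mm = 8) {
  if (!is.null(segments) && nrow(segments) > 0) {
    stopifnot(all(c("x1", "y1", "z1", "x2", "y2", "z2", "radius",
                    "intensity") %in% names(segments)),
              all(segments$radius > 0))
  }
  if (!is.null(junctions) && nrow(junctions) > 0) {
    stopifnot(all(c("x", "y", "z", "d_large", "d_small") %in%
                    names(junctions)),
              all(junctions$d_large >= junctions$d_small),
              all(junctions$d_small > 0))
    for (j in seq_len(nrow(junctions))) {
      p <- as.numeric(junctions[j, c("x", "y", "z")])
      on_axis <- 0L
      for (s in seq_len(nrow(segments))) {
        a <- as.numeric(segments[s, c("x1", "y1", "z1")])
        b <- as.numeric(segments[s, c("x2", "y2", "z2")])
        if (point_segment_distance(matrix(p, 1), a, b) < 1e-6)
          on_axis <- on_axis + 1L
      }
      if (on_axis < 2L)
        stop(sprintf("junction %d does not lie on at least 2 segment axes", j))
    }
  }
  structure(list(segments = segments, junctions = junctions,
                 background = background, noise_sigma = noise_sigma,
                 margin_mm = margin_mm),
            class = "vessel_phantom_spec")
}

# Distance from points P (n x 3) to segment [a, b].
point_segment_distance <- function(p, a, b) {
  ab <- b - a
  len2 <- sum(ab^2)
  rel <- sweep(p, 2, a)
  tt <- if (len2 > 0) pmin(pmax(rel %*% ab / len2, 0), 1) else rep(0, nrow(p))
  proj <- outer(as.numeric(tt), ab)
  sqrt(rowSums((rel - proj)^2))
}

#' Rasterise a vessel phantom to a volume with ground-truth landmarks
#'
#' Renders the tube segments of a [vessel_phantom_spec()] on a regular
#' grid. Each voxel takes the background value plus the maximum over
#' segments of a soft tube profile: full segment intensity deeper than
#' half a voxel inside the tube wall, ramping linearly to background
#' over one voxel. Gaussian noise is added when `noise_sigma > 0`
#' (seed the RNG beforehand for reproducibility). Junctions are emitted
#' as landmarks typed by the diameter-ratio rule ([classify_bifurcation()]);
#' a junction whose smaller branch radius is below the grid spacing is
#' flagged as under-resolved.
#'
#' @param spec A [vessel_phantom_spec()].
#' @param spacing Isotropic grid spacing in mm (default 1).
#' @return List with `volume` (a [volume()]) and `landmarks` (a landmark
#'   data frame, see [landmark_frame()]).
#' @export
make_vessel_phantom <- function(spec, spacing = 1) {
  stopifnot(inherits(spec, "vessel_phantom_spec"), spacing > 0)
  segs <- spec$segments
  if (is.null(segs) || nrow(segs) == 0L) {
    d <- rep(max(2L, as.integer(round(20 / spacing))), 3)
    vox <- array(spec$background, dim = d)
    if (spec$noise_sigma > 0)
      vox <- vox + array(stats::rnorm(prod(d), 0, spec$noise_sigma), dim = d)
    return(list(volume = volume(vox, spacing = rep(spacing, 3)),
                landmarks = landmark_frame()))
  }
  ends <- rbind(as.matrix(segs[, c("x1", "y1", "z1")]),
                as.matrix(segs[, c("x2", "y2", "z2")]))
  pad <- max(segs$radius) + spec$margin_mm
  lo <- apply(ends, 2, min) - pad
  hi <- apply(ends, 2, max) + pad
  d <- as.integer(ceiling((hi - lo) / spacing)) + 1L
  vol0 <- volume(array(0, dim = d), spacing = rep(spacing, 3), origin = lo)
  worlds <- voxel_to_world(vol0, index_grid(d))
  excess <- rep(0, nrow(worlds)) # max over segments of w * (intensity - bg)
  h <- spacing
  for (s in seq_len(nrow(segs))) {
    a <- as.numeric(segs[s, c("x1", "y1", "z1")])
    b <- as.numeric(segs[s, c("x2", "y2", "z2")])
    dist <- point_segment_distance(worlds, a, b)
    w <- pmin(pmax((segs$radius[s] + h / 2 - dist) / h, 0), 1)
    excess <- pmax(excess, w * (segs$intensity[s] - spec$background))
  }
  vox <- array(spec$background + excess, dim = d)
  if (spec$noise_sigma > 0)
    vox <- vox + array(stats::rnorm(prod(d), 0, spec$noise_sigma), dim = d)
  out_vol <- volume(vox, spacing = rep(spacing, 3), origin = lo)

  lms <- landmark_frame()
  if (!is.null(spec$junctions) && nrow(spec$junctions) > 0) {
    jn <- spec$junctions
    lms <- landmark_frame(
      id = sprintf("J%02d", seq_len(nrow(jn))),
      x_mm = jn$x, y_mm = jn$y, z_mm = jn$z,
      type = vapply(seq_len(nrow(jn)), function(i)
        classify_bifurcation(jn$d_large[i], jn$d_small[i]), character(1)),
      flagged = as.integer(jn$d_small / 2 < spacing),
      substrate = "none")
  }
  list(volume = out_vol, landmarks = lms)
}

#' Construct a phantom deformation (rotation + scale + sinusoid)
#'
#' The exact forward point map used by the digital phantom studies:
#' `p_a = pivot + scale * R * (p - pivot)` followed by a per-axis
#' sinusoidal displacement `p' = p_a + A * sin(2*pi*p_a/P + phi)`.
#' The sinusoid must satisfy `|A_i * 2*pi / P_i| < 0.9` on every axis so
#' the warp stays invertible (a contraction for the fixed-point
#' inverse).
#'
#' @param rotation_axis Unit 3-vector (normalised internally).
#' @param rotation_angle Angle in degrees, in `[0, 50]`.
#' @param scale Global scale factor, in `[0.9, 1.1]`.
#' @param sinus_amplitude Per-axis amplitude, mm (length 3).
#' @param sinus_period Per-axis period, mm (length 3, > 0).
#' @param sinus_phase Per-axis phase, radians (length 3).
#' @param pivot Rotation/scale pivot, world mm (usually the patch
#'   centre).
#' @return A `phantom_transform` list.
#' @export
phantom_transform <- function(rotation_axis = c(0, 0, 1), rotation_angle = 0,
                              scale = 1, sinus_amplitude = c(0, 0, 0),
                              sinus_period = c(100, 100, 100),
                              sinus_phase = c(0, 0, 0), pivot = c(0, 0, 0)) {
  rotation_axis <- as.numeric(rotation_axis)
  nrm <- sqrt(sum(rotation_axis^2))
  if (nrm == 0) stop("rotation axis must be non-zero")
  rotation_axis <- rotation_axis / nrm
  stopifnot(rotation_angle >= 0, rotation_angle <= 50,
            scale >= 0.9, scale <= 1.1,
            length(sinus_amplitude) == 3, length(sinus_period) == 3,
            all(sinus_period > 0), length(sinus_phase) == 3)
  if (any(abs(sinus_amplitude * 2 * pi / sinus_period) >= 0.9))
    stop("sinusoid violates invertibility: need |A*2*pi/P| < 0.9 per axis")
  structure(list(rotation_axis = rotation_axis,
                 rotation_angle = rotation_angle, scale = scale,
                 sinus_amplitude = as.numeric(sinus_amplitude),
                 sinus_period = as.numeric(sinus_period),
                 sinus_phase = as.numeric(sinus_phase),
                 pivot = as.numeric(pivot)),
            class = "phantom_transform")
}

# Rodrigues rotation matrix for a unit axis and angle in degrees.
rotation_matrix <- function(axis, angle_deg) {
  th <- angle_deg * pi / 180
  k <- axis
  kx <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
  diag(3) + sin(th) * kx + (1 - cos(th)) * (kx %*% kx)
}

#' Draw a random phantom deformation
#'
#' Samples a [phantom_transform()] with the axis uniform on the sphere,
#' angle uniform on \[0, 50\] degrees, scale uniform on \[0.9, 1.1\],
#' per-axis sinusoid amplitude uniform on `amplitude_range` (default
#' \[0, 5\] mm), period uniform on `period_range` (default \[60, 120\]
#' mm) and phase uniform on \[0, 2*pi). With these default ranges the
#' invertibility bound `|A*2*pi/P| < 0.9` always holds. Draws are taken
#' from the current RNG state; use `set.seed()` (or the `seed`
#' argument) for reproducibility.
#'
#' @param seed Optional integer seed applied with `set.seed()`.
#' @param pivot Pivot point (world mm) for rotation and scaling.
#' @param amplitude_range,period_range Length-2 ranges, mm.
#' @return A [phantom_transform()].
#' @export
sample_phantom_transform <- function(seed = NULL, pivot = c(0, 0, 0),
                                     amplitude_range = c(0, 5),
                                     period_range = c(60, 120)) {
  if (!is.null(seed)) set.seed(seed)
  ax <- stats::rnorm(3)
  while (sum(ax^2) < 1e-12) ax <- stats::rnorm(3)
  for (attempt in 1:100) {
    amp <- stats::runif(3, amplitude_range[1], amplitude_range[2])
    per <- stats::runif(3, period_range[1], period_range[2])
    if (all(abs(amp * 2 * pi / per) < 0.9)) break
  }
  phantom_transform(
    rotation_axis = ax / sqrt(sum(ax^2)),
    rotation_angle = stats::runif(1, 0, 50),
    scale = stats::runif(1, 0.9, 1.1),
    sinus_amplitude = amp, sinus_period = per,
    sinus_phase = stats::runif(3, 0, 2 * pi),
    pivot = pivot)
}

#' Map points through a phantom transform
#'
#' `map_point_forward` applies the exact closed-form forward map;
#' `map_point_inverse` inverts it by composing the exact affine inverse
#' with a fixed-point inversion of the sinusoidal displacement
#' (guaranteed to converge because the warp is a contraction under the
#' invertibility invariant).
#'
#' @param p Length-3 vector or n x 3 matrix of world-mm points.
#' @param transform A [phantom_transform()].
#' @param tol Fixed-point convergence tolerance in mm (default 1e-6).
#' @param max_iter Maximum fixed-point iterations (default 100).
#' @return Mapped point(s), same shape as `p`.
#' @export
map_point_forward <- function(p, transform) {
  stopifnot(inherits(transform, "phantom_transform"))
  single <- !is.matrix(p)
  pm <- as_point_matrix(p)
  R <- rotation_matrix(transform$rotation_axis, transform$rotation_angle)
  pa <- sweep(sweep(pm, 2, transform$pivot) %*% t(R) * transform$scale,
              2, transform$pivot, "+")
  arg <- sweep(sweep(pa, 2, 2 * pi / transform$sinus_period, "*"),
               2, transform$sinus_phase, "+")
  out <- pa + sweep(sin(arg), 2, transform$sinus_amplitude, "*")
  if (single) as.numeric(out[1L, ]) else out
}

#' @rdname map_point_forward
#' @export
map_point_inverse <- function(p, transform, tol = 1e-6, max_iter = 100L) {
  stopifnot(inherits(transform, "phantom_transform"))
  single <- !is.matrix(p)
  pm <- as_point_matrix(p)
  x <- pm
  converged <- FALSE
  for (i in seq_len(max_iter)) {
    arg <- sweep(sweep(x, 2, 2 * pi / transform$sinus_period, "*"),
                 2, transform$sinus_phase, "+")
    x_new <- pm - sweep(sin(arg), 2, transform$sinus_amplitude, "*")
    if (max(abs(x_new - x)) < tol) {
      x <- x_new
      converged <- TRUE
      break
    }
    x <- x_new
  }
  if (!converged)
    stop("fixed-point inversion did not converge: transform not invertible")
  R <- rotation_matrix(transform$rotation_axis, transform$rotation_angle)
  out <- sweep(sweep(x, 2, transform$pivot) %*% R / transform$scale,
               2, transform$pivot, "+")
  if (single) as.numeric(out[1L, ]) else out
}

#' Warp a volume with a phantom transform
#'
#' Produces the "second image" of a digital phantom pair: the output
#' voxel at world position `q` takes the trilinearly interpolated input
#' intensity at `T^-1(q)` (backward warping), so that a structure at
#' `p` in the input appears at `map_point_forward(p)` in the output.
#' The output reuses the input grid geometry.
#'
#' @param vol A [volume()].
#' @param transform A [phantom_transform()].
#' @param fill Intensity for source points outside the input volume
#'   (default -1000).
#' @return A warped [volume()].
#' @export
apply_transform_to_volume <- function(vol, transform, fill = -1000) {
  stopifnot(is_volume(vol), inherits(transform, "phantom_transform"))
  d <- dim(vol$voxels)
  q <- voxel_to_world(vol, index_grid(d))
  src <- map_point_inverse(q, transform)
  idx <- world_to_voxel(vol, src)
  vals <- interp_trilinear(vol$voxels, idx, fill = fill)
  out <- vol
  out$voxels <- array(vals, dim = d)
  out
}

#' Degrade image quality (smoothing + noise)
#'
#' Simulates lower-quality acquisitions by Gaussian smoothing followed
#' by additive Gaussian noise, for stress-testing refinement and
#' registration evaluation on degraded inputs.
#'
#' @param vol A [volume()].
#' @param noise_sigma Noise sigma in HU (>= 0).
#' @param smooth_sigma Smoothing sigma in voxels (>= 0).
#' @param seed Optional integer seed applied with `set.seed()`.
#' @return A degraded [volume()].
#' @export
degrade_image <- function(vol, noise_sigma = 0, smooth_sigma = 0,
                          seed = NULL) {
  stopifnot(is_volume(vol), noise_sigma >= 0, smooth_sigma >= 0)
  if (!is.null(seed)) set.seed(seed)
  out <- vol
  if (smooth_sigma > 0)
    out$voxels <- smooth_gaussian(out$voxels, smooth_sigma)
  if (noise_sigma > 0)
    out$voxels <- out$voxels +
      array(stats::rnorm(prod(dim(out$voxels)), 0, noise_sigma),
            dim = dim(out$voxels))
  out
}

#' Build an observer-study patch pair
#'
#' Prepares the blinded patch pair used to measure manual landmarking
#' variability: patch 1 is centred exactly on landmark 1 (its position
#' is exported); patch 2 is centred on landmark 2 shifted by a random
#' integer offset of at most `max_offset_slices` voxels per axis, and
#' the landmark position in patch 2 is withheld (returned separately as
#' the scoring truth).
#'
#' @param vol1,vol2 The two [volume()]s of an image pair.
#' @param lm1,lm2 One-row landmark data frames (the matched pair).
#' @param size Patch size in mm (default 100).
#' @param max_offset_slices Maximum |offset| in voxels per axis
#'   (default 3).
#' @param seed Optional integer seed applied with `set.seed()`.
#' @return List with `patch1`, `visible_position` (world mm), `patch2`,
#'   `hidden_truth` (world mm, landmark 2) and `offset_voxels`.
#' @export
make_observer_patch_pair <- function(vol1, vol2, lm1, lm2, size = 100,
                                     max_offset_slices = 3L, seed = NULL) {
  stopifnot(is_volume(vol1), is_volume(vol2))
  if (!is.null(seed)) set.seed(seed)
  p1 <- c(lm1$x_mm, lm1$y_mm, lm1$z_mm)
  p2 <- c(lm2$x_mm, lm2$y_mm, lm2$z_mm)
  off <- if (max_offset_slices > 0)
    sample(seq(-max_offset_slices, max_offset_slices), 3, replace = TRUE)
  else c(0L, 0L, 0L)
  off_mm <- as.numeric(vol2$orientation %*% (off * vol2$spacing))
  list(patch1 = extract_patch(vol1, p1, size),
       visible_position = p1,
       patch2 = extract_patch(vol2, p2 + off_mm, size),
       hidden_truth = p2,
       offset_voxels = off)
}

#' Convenience Y-junction phantom specification
#'
#' Builds a [vessel_phantom_spec()] for a single Y-shaped bifurcation:
#' a trunk running along `-z` from the junction at the origin and two
#' branches leaving the junction at the given polar angles. The
#' junction is emitted as the ground-truth landmark, typed by the
#' trunk/branch diameter ratio.
#'
#' @param r_trunk Trunk radius, mm (default 3).
#' @param r_branch Length-2 branch radii, mm (default `c(3, 3)`).
#' @param branch_angles Length-2 polar angles of the branches from the
#'   `+z` axis, radians (default `c(pi/5, -pi/4)`).
#' @param length Segment length, mm (default 35).
#' @param intensity Tube intensity, HU (default 300, a typical
#'   contrast-enhanced vessel before windowing).
#' @param background Background HU (default -1000).
#' @param noise_sigma Additive noise sigma, HU (default 0).
#' @return A [vessel_phantom_spec()] with one junction at the origin.
#' @export
yjunction_phantom_spec <- function(r_trunk = 3, r_branch = c(3, 3),
                                   branch_angles = c(pi / 5, -pi / 4),
                                   length = 35, intensity = 300,
                                   background = -1000, noise_sigma = 0) {
  stopifnot(length(r_branch) == 2L, length(branch_angles) == 2L)
  ends <- rbind(length * c(0, 0, -1),
                length * c(sin(branch_angles[1]), 0, cos(branch_angles[1])),
                length * c(sin(branch_angles[2]), 0.2, cos(branch_angles[2])))
  segs <- data.frame(x1 = 0, y1 = 0, z1 = 0,
                     x2 = ends[, 1], y2 = ends[, 2], z2 = ends[, 3],
                     radius = c(r_trunk, r_branch),
                     intensity = intensity)
  dmax <- 2 * max(r_trunk, r_branch)
  dmin <- 2 * min(r_trunk, r_branch)
  vessel_phantom_spec(segs,
                      junctions = data.frame(x = 0, y = 0, z = 0,
                                             d_large = dmax, d_small = dmin),
                      background = background, noise_sigma = noise_sigma)
}
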