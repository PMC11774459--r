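#' 3-D image volume with world-space geometry
#'
#' A `volume` is the package's container for a scalar 3-D image grid
#' (CT intensities in Hounsfield units, binary masks, or vesselness maps)
#' together with its world-space geometry. World coordinates follow the
#' NIfTI convention: `world = orientation %*% diag(spacing) %*% index + origin`
#' with 0-based voxel indices, all positions in millimetres.
#'
#' @param voxels Numeric 3-D array of voxel values.
#' @param spacing Numeric length-3 vector, mm per voxel along each axis;
#'   all components must be positive.
#' @param origin Numeric length-3 vector, world position (mm) of voxel
#'   index (0, 0, 0).
#' @param orientation 3x3 direction cosine matrix; must be orthonormal
#'   (`|det| = 1` within 1e-6). Defaults to the identity.
#' @return An object of class `volume`.
#' @export
volume <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                   orientation = diag(3)) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("'voxels' must be a 3-D array")
  storage.mode(voxels) <- "double"
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  orientation <- matrix(as.numeric(orientation), 3L, 3L)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("'spacing' must be 3 positive finite values")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("'origin' must be 3 finite values")
  if (abs(abs(det(orientation)) - 1) > 1e-6 ||
      max(abs(crossprod(orientation) - diag(3))) > 1e-6)
    stop("'orientation' must be orthonormal (|det| = 1)")
  if (any(!is.finite(voxels)))
    stop("all voxel values must be finite")
  structure(list(voxels = voxels, spacing = spacing, origin = origin,
                 orientation = orientation),
            class = "volume")
}

#' @export
print.volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<volume> %d x %d x %d voxels, spacing %s mm, origin (%s) mm\n",
              d[1], d[2], d[3],
              paste(signif(x$spacing, 4), collapse = " x "),
              paste(signif(x$origin, 4), collapse = ", ")))
  cat(sprintf("  intensity range [%g, %g]\n",
              min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' @export
dim.volume <- function(x) dim(x$voxels)

is_volume <- function(x) inherits(x, "volume")

is_isotropic <- function(vol, tol = 1e-6) {
  diff(range(vol$spacing)) <= tol * mean(vol$spacing)
}

#' Convert between world coordinates and continuous voxel indices
#'
#' Exact affine maps between world millimetres and 0-based (possibly
#' fractional) voxel indices of a [volume()]. `voxel_to_world` is the
#' inverse of `world_to_voxel` to machine precision.
#'
#' @param vol A [volume()].
#' @param p Numeric length-3 vector or n x 3 matrix of points. World mm
#'   for `world_to_voxel`, continuous 0-based indices for `voxel_to_world`.
#' @return A matrix of the same shape as `p` (a single point is returned
#'   as a length-3 vector).
#' @export
world_to_voxel <- function(vol, p) {
  single <- !is.matrix(p)
  pm <- as_point_matrix(p)
  idx <- sweep(pm, 2, vol$origin) %*% vol$orientation # row form of S^-1 O^T (p - o)
  idx <- sweep(idx, 2, vol$spacing, "/")
  if (single) as.numeric(idx[1L, ]) else idx
}

#' @rdname world_to_voxel
#' @export
voxel_to_world <- function(vol, p) {
  single <- !is.matrix(p)
  pm <- as_point_matrix(p)
  w <- sweep(pm, 2, vol$spacing, "*") %*% t(vol$orientation)
  w <- sweep(w, 2, vol$origin, "+")
  if (single) as.numeric(w[1L, ]) else w
}

as_point_matrix <- function(p) {
  if (is.matrix(p)) {
    if (ncol(p) != 3L) stop("points must have 3 columns")
    p
  } else {
    if (length(p) != 3L) stop("a point must have 3 components")
    matrix(as.numeric(p), 1L, 3L)
  }
}

# Trilinear interpolation of a 3-D array at continuous 0-based indices.
# idx: n x 3 matrix. Points outside [0, dim-1] (with `tol` slack snapped
# to the border) receive `fill`; fill = NA keeps them NA.
interp_trilinear <- function(arr, idx, fill = NA_real_, tol = 1e-9) {
  d <- dim(arr)
  n <- nrow(idx)
  x <- pmin(pmax(idx[, 1], -tol), d[1] - 1 + tol)
  y <- pmin(pmax(idx[, 2], -tol), d[2] - 1 + tol)
  z <- pmin(pmax(idx[, 3], -tol), d[3] - 1 + tol)
  outside <- idx[, 1] < -tol | idx[, 1] > d[1] - 1 + tol |
             idx[, 2] < -tol | idx[, 2] > d[2] - 1 + tol |
             idx[, 3] < -tol | idx[, 3] > d[3] - 1 + tol
  x <- pmin(pmax(x, 0), d[1] - 1); y <- pmin(pmax(y, 0), d[2] - 1)
  z <- pmin(pmax(z, 0), d[3] - 1)
  i0 <- pmin(floor(x), d[1] - 2); j0 <- pmin(floor(y), d[2] - 2)
  k0 <- pmin(floor(z), d[3] - 2)
  i0 <- pmax(i0, 0); j0 <- pmax(j0, 0); k0 <- pmax(k0, 0)
  fx <- x - i0; fy <- y - j0; fz <- z - k0
  s1 <- d[1]; s2 <- d[1] * d[2]
  base <- 1 + i0 + j0 * s1 + k0 * s2
  v000 <- arr[base];           v100 <- arr[base + 1]
  v010 <- arr[base + s1];      v110 <- arr[base + 1 + s1]
  v001 <- arr[base + s2];      v101 <- arr[base + 1 + s2]
  v011 <- arr[base + s1 + s2]; v111 <- arr[base + 1 + s1 + s2]
  w00 <- v000 * (1 - fx) + v100 * fx
  w10 <- v010 * (1 - fx) + v110 * fx
  w01 <- v001 * (1 - fx) + v101 * fx
  w11 <- v011 * (1 - fx) + v111 * fx
  w0 <- w00 * (1 - fy) + w10 * fy
  w1 <- w01 * (1 - fy) + w11 * fy
  out <- w0 * (1 - fz) + w1 * fz
  if (any(outside)) out[outside] <- fill
  out
}

# Nearest-neighbour lookup at continuous 0-based indices (for masks).
interp_nearest <- function(arr, idx, fill = NA_real_, tol = 1e-9) {
  d <- dim(arr)
  i <- round(idx[, 1]); j <- round(idx[, 2]); k <- round(idx[, 3])
  outside <- i < 0 | i > d[1] - 1 | j < 0 | j > d[2] - 1 | k < 0 | k > d[3] - 1
  i <- pmin(pmax(i, 0), d[1] - 1); j <- pmin(pmax(j, 0), d[2] - 1)
  k <- pmin(pmax(k, 0), d[3] - 1)
  out <- arr[1 + i + j * d[1] + k * d[1] * d[2]]
  if (any(outside)) out[outside] <- fill
  out
}

# 0-based index grid (n-points x 3) for a volume of dimensions d.
index_grid <- function(d) {
  cbind(rep.int(seq_len(d[1]) - 1, d[2] * d[3]),
        rep.int(rep(seq_len(d[2]) - 1, each = d[1]), d[3]),
        rep(seq_len(d[3]) - 1, each = d[1] * d[2]))
}

geometry_equal <- function(a, b, tol = 1e-4) {
  identical(dim(a$voxels), dim(b$voxels)) &&
    max(abs(a$spacing - b$spacing)) <= tol &&
    max(abs(a$origin - b$origin)) <= tol &&
    max(abs(a$orientation - b$orientation)) <= tol
}
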