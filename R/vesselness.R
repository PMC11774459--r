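#' Configuration for multiscale Hessian vesselness
#'
#' Parameters of the Frangi-style 3-D line filter used to build the
#' automatic vessel-mask fallback. The filter responds to bright
#' tubular structures: at each scale the Gaussian-scale-normalised
#' Hessian is eigen-decomposed and voxels with one near-zero and two
#' large negative eigenvalues (a bright line) score highly.
#'
#' @param scales Gaussian scales in mm (default `c(0.7, 1.4, 2.1, 2.8)`,
#'   matching vessel radii of roughly 1-3 mm at the 0.7 mm working
#'   resolution).
#' @param alpha Plate-vs-line sensitivity (default 0.5).
#' @param beta Blob sensitivity (default 0.5).
#' @param gamma Structure-noise sensitivity; `NULL` (default) uses half
#'   the maximum Hessian norm per scale.
#' @param bright_on_dark If `TRUE` (default) respond to bright vessels
#'   on a dark background.
#' @return A `vesselness_config` list.
#' @export
vesselness_config <- function(scales = c(0.7, 1.4, 2.1, 2.8),
                              alpha = 0.5, beta = 0.5, gamma = NULL,
                              bright_on_dark = TRUE) {
  stopifnot(all(scales > 0), alpha > 0, beta > 0,
            is.null(gamma) || gamma > 0)
  structure(list(scales = scales, alpha = alpha, beta = beta,
                 gamma = gamma, bright_on_dark = bright_on_dark),
            class = "vesselness_config")
}

# Eigenvalues of a field of symmetric 3x3 matrices (vectorised analytic
# solution); returns a list of three vectors sorted by absolute value,
# |e1| <= |e2| <= |e3|.
eig_sym3_sorted_abs <- function(a11, a22, a33, a12, a13, a23) {
  q <- (a11 + a22 + a33) / 3
  p2 <- (a11 - q)^2 + (a22 - q)^2 + (a33 - q)^2 +
    2 * (a12^2 + a13^2 + a23^2)
  p <- sqrt(pmax(p2, 0) / 6)
  safe <- p > 0
  pg <- ifelse(safe, p, 1)
  b11 <- (a11 - q) / pg; b22 <- (a22 - q) / pg; b33 <- (a33 - q) / pg
  b12 <- a12 / pg; b13 <- a13 / pg; b23 <- a23 / pg
  detb <- b11 * (b22 * b33 - b23^2) - b12 * (b12 * b33 - b23 * b13) +
    b13 * (b12 * b23 - b22 * b13)
  r <- pmin(pmax(detb / 2, -1), 1)
  phi <- acos(r) / 3
  e1 <- q + 2 * p * cos(phi)
  e3 <- q + 2 * p * cos(phi + 2 * pi / 3)
  e2 <- 3 * q - e1 - e3
  e1[!safe] <- q[!safe]; e2[!safe] <- q[!safe]; e3[!safe] <- q[!safe]
  # sort by |.|: 3-element compare-swap network
  swp <- function(a, b) {
    s <- abs(a) > abs(b)
    list(lo = ifelse(s, b, a), hi = ifelse(s, a, b))
  }
  s1 <- swp(e1, e2); e1 <- s1$lo; e2 <- s1$hi
  s2 <- swp(e2, e3); e2 <- s2$lo; e3 <- s2$hi
  s3 <- swp(e1, e2); e1 <- s3$lo; e2 <- s3$hi
  list(e1 = e1, e2 = e2, e3 = e3)
}

# Scale-normalised Hessian components of arr at sigma (voxels):
# smooth, then central differences twice, times sigma^2.
hessian_at_scale <- function(arr, sigma) {
  sm <- smooth_gaussian(arr, sigma)
  g <- lapply(1:3, function(ax) central_diff(sm, ax))
  h <- list(
    a11 = central_diff(g[[1]], 1), a22 = central_diff(g[[2]], 2),
    a33 = central_diff(g[[3]], 3), a12 = central_diff(g[[1]], 2),
    a13 = central_diff(g[[1]], 3), a23 = central_diff(g[[2]], 3))
  lapply(h, function(x) x * sigma^2)
}

#' Multiscale Hessian vesselness of an isotropic patch
#'
#' Computes the per-voxel maximum over scales of the Frangi line
#' measure. Bright tubular structures score near 1; plates, blobs and
#' background score near 0. The measure is invariant to adding a
#' constant to the image.
#'
#' @param patch An isotropic [volume()].
#' @param config A [vesselness_config()].
#' @return A [volume()] of vesselness values in `[0, 1]`.
#' @export
vesselness <- function(patch, config = vesselness_config()) {
  if (!is_volume(patch)) stop("'patch' must be a volume")
  if (!is_isotropic(patch))
    stop("'patch' must be isotropically resampled")
  arr <- patch$voxels
  d <- dim(arr)
  best <- array(0, dim = d)
  for (s in config$scales) {
    sig <- s / patch$spacing[1]
    h <- hessian_at_scale(arr, sig)
    ev <- eig_sym3_sorted_abs(h$a11, h$a22, h$a33, h$a12, h$a13, h$a23)
    e1 <- ev$e1; e2 <- ev$e2; e3 <- ev$e3
    tiny <- 1e-12
    ra <- abs(e2) / (abs(e3) + tiny)
    rb <- abs(e1) / sqrt(abs(e2 * e3) + tiny)
    s2 <- e1^2 + e2^2 + e3^2
    gamma <- config$gamma
    if (is.null(gamma)) gamma <- 0.5 * sqrt(max(s2))
    if (gamma <= 0) next
    v <- (1 - exp(-ra^2 / (2 * config$alpha^2))) *
      exp(-rb^2 / (2 * config$beta^2)) *
      (1 - exp(-s2 / (2 * gamma^2)))
    if (config$bright_on_dark) v[e2 > 0 | e3 > 0] <- 0
    else v[e2 < 0 | e3 < 0] <- 0
    best <- pmax(best, array(v, dim = d))
  }
  out <- patch
  out$voxels <- array(pmin(pmax(best, 0), 1), dim = d)
  out
}

#' Region growing of a connected supra-threshold component
#'
#' Returns the 26-connected component of `{field >= threshold}` that
#' contains the seed voxel, as a binary volume. If the seed itself is
#' below threshold the mask is empty.
#'
#' @param field A [volume()] (e.g. a vesselness map).
#' @param seed Integer 1-based voxel index, length 3.
#' @param threshold Scalar threshold.
#' @return A binary [volume()] (0/1).
#' @export
region_grow <- function(field, seed, threshold) {
  if (!is_volume(field)) stop("'field' must be a volume")
  d <- dim(field$voxels)
  seed <- as.integer(round(seed))
  if (length(seed) != 3L || any(seed < 1L) || any(seed > d))
    stop("seed lies outside the field")
  above <- field$voxels >= threshold
  out <- field
  out$voxels <- array(0, dim = d)
  if (!above[seed[1], seed[2], seed[3]]) return(out)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  visited <- array(FALSE, dim = d)
  visited[seed[1], seed[2], seed[3]] <- TRUE
  frontier <- matrix(seed, 1L, 3L)
  while (nrow(frontier) > 0L) {
    cand <- frontier[rep(seq_len(nrow(frontier)), each = nrow(offs)), ,
                     drop = FALSE] +
      offs[rep(seq_len(nrow(offs)), nrow(frontier)), , drop = FALSE]
    keep <- cand[, 1] >= 1 & cand[, 1] <= d[1] &
            cand[, 2] >= 1 & cand[, 2] <= d[2] &
            cand[, 3] >= 1 & cand[, 3] <= d[3]
    cand <- cand[keep, , drop = FALSE]
    if (nrow(cand) == 0L) break
    lin <- cand[, 1] + (cand[, 2] - 1L) * d[1] + (cand[, 3] - 1L) * d[1] * d[2]
    keep <- above[lin] & !visited[lin] & !duplicated(lin)
    cand <- cand[keep, , drop = FALSE]
    if (nrow(cand) == 0L) break
    lin <- cand[, 1] + (cand[, 2] - 1L) * d[1] + (cand[, 3] - 1L) * d[1] * d[2]
    visited[lin] <- TRUE
    frontier <- cand
  }
  out$voxels <- array(as.numeric(visited), dim = d)
  out
}

#' Automatic vessel mask for the sphere-growing fallback
#'
#' Composes [vesselness()] (normalised to a unit maximum) with
#' [region_grow()] from the landmark seed. An empty mask signals that
#' the automatic fallback failed and the caller should move down the
#' substrate ladder.
#'
#' @param patch An isotropic [volume()].
#' @param seed Integer 1-based voxel index of the landmark.
#' @param vconfig A [vesselness_config()].
#' @param threshold Threshold on the max-normalised vesselness
#'   (default 0.05).
#' @return A binary [volume()]; all-zero when the fallback fails.
#' @export
auto_vessel_mask <- function(patch, seed, vconfig = vesselness_config(),
                             threshold = 0.05) {
  v <- vesselness(patch, vconfig)
  mx <- max(v$voxels)
  if (mx > 0) v$voxels <- v$voxels / mx
  region_grow(v, seed, threshold)
}
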