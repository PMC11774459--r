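#' Landmark table constructor
#'
#' Landmarks are kept in a plain data frame with one row per landmark:
#' `id` (label), `case` (case label), `image` (1 or 2), `x_mm, y_mm,
#' z_mm` (world-mm position), `type` (`"type1"`, `"type2"` or
#' `"unrefined"`), `flagged` (0/1) and `substrate` (`"image"`,
#' `"auto_mask"`, `"manual_mask"` or `"none"`). Positions are always
#' world millimetres, never voxel indices, so tables are portable
#' across images with different voxel sizes.
#'
#' @param id,case,image,x_mm,y_mm,z_mm,type,flagged,substrate Column
#'   values, recycled to a common length.
#' @return A data frame with the landmark schema.
#' @export
landmark_frame <- function(id = character(0), case = "case", image = 1L,
                           x_mm = numeric(0), y_mm = numeric(0),
                           z_mm = numeric(0), type = "unrefined",
                           flagged = 0L, substrate = "none") {
  n <- length(id)
  df <- data.frame(id = as.character(id), case = rep_len(as.character(case), n),
                   image = rep_len(as.integer(image), n),
                   x_mm = as.numeric(x_mm), y_mm = as.numeric(y_mm),
                   z_mm = as.numeric(z_mm),
                   type = rep_len(as.character(type), n),
                   flagged = rep_len(as.integer(flagged), n),
                   substrate = rep_len(as.character(substrate), n),
                   stringsAsFactors = FALSE)
  bad <- !df$type %in% c("type1", "type2", "unrefined")
  if (any(bad)) stop("landmark 'type' must be type1, type2 or unrefined")
  df
}

#' Classify a bifurcation by branch diameter ratio
#'
#' A bifurcation is type 2 when the larger vessel is at least 2.5 times
#' the diameter of the smaller one (boundary inclusive); otherwise it is
#' type 1. Type-1 bifurcations are refined automatically by sphere
#' growing; type-2 points are placed geometrically at the intersection
#' of the small-vessel centreline with the large-vessel surface.
#'
#' @param d_large,d_small Branch diameters in mm, `d_large >= d_small > 0`.
#' @param ratio Classification threshold (default 2.5).
#' @return `"type1"` or `"type2"`.
#' @export
classify_bifurcation <- function(d_large, d_small, ratio = 2.5) {
  if (!is.finite(d_large) || !is.finite(d_small) || d_small <= 0 ||
      d_large < d_small)
    stop("need d_large >= d_small > 0")
  if (d_large / d_small >= ratio) "type2" else "type1"
}

#' Geometric type-2 bifurcation point
#'
#' Locates the point where the centreline of the smaller vessel crosses
#' the surface of the larger vessel: the first crossing of the polyline
#' with the 0.5 level of the trilinearly interpolated vessel mask,
#' refined by bisection to `tol` mm. Segments are densified to half the
#' voxel spacing before crossing detection, making the result invariant
#' to the polyline's sampling density.
#'
#' @param centerline n x 3 matrix of world-mm points along the smaller
#'   vessel's centreline, ordered from outside the larger vessel inward
#'   (or vice versa).
#' @param vessel_mask Binary [volume()] of the larger vessel.
#' @param tol Bisection tolerance in mm (default 1e-3).
#' @return Length-3 world-mm point on the mask surface.
#' @export
type2_point <- function(centerline, vessel_mask, tol = 1e-3) {
  stopifnot(is_volume(vessel_mask))
  pl <- as_point_matrix(centerline)
  if (nrow(pl) < 1L) stop("empty centerline")
  step <- 0.5 * min(vessel_mask$spacing)
  dense <- pl[1, , drop = FALSE]
  if (nrow(pl) > 1L) {
    for (i in seq_len(nrow(pl) - 1L)) {
      a <- pl[i, ]; b <- pl[i + 1L, ]
      len <- sqrt(sum((b - a)^2))
      k <- max(1L, ceiling(len / step))
      tt <- seq_len(k) / k
      dense <- rbind(dense, sweep(outer(tt, b - a), 2, a, "+"))
    }
  }
  f <- function(pts) {
    interp_trilinear(vessel_mask$voxels,
                     world_to_voxel(vessel_mask, as_point_matrix(pts)),
                     fill = 0) - 0.5
  }
  v <- f(dense)
  if (abs(v[1]) < 1e-12) return(as.numeric(dense[1, ]))
  cross <- which(v[-1] * v[1] <= 0)
  if (length(cross) == 0L)
    stop("centerline never crosses the vessel surface")
  i <- cross[1]
  a <- dense[i, ]; b <- dense[i + 1L, ]
  fa <- v[i]
  while (sqrt(sum((b - a)^2)) > tol) {
    m <- (a + b) / 2
    fm <- f(matrix(m, 1))
    if (fa * fm <= 0) b <- m else { a <- m; fa <- fm }
  }
  as.numeric((a + b) / 2)
}

#' Project landmarks through a deformation vector field
#'
#' Applies `p' = p + DVF(p)` with trilinear interpolation of the
#' displacement at each landmark position, the standard way of mapping
#' image-1 landmarks into image-2 space with a registration's DVF. The
#' DVF convention is displacement in mm from image-1 space to image-2
#' space, sampled at image-1 world coordinates. Landmarks outside the
#' DVF grid are left unmoved and marked in an `out_of_grid` column.
#'
#' @param landmarks Landmark data frame ([landmark_frame()]).
#' @param dvf A [vector_field()] in mm.
#' @return The landmark frame with updated positions and an
#'   `out_of_grid` logical column.
#' @export
project_landmarks_through_dvf <- function(landmarks, dvf) {
  stopifnot(is.data.frame(landmarks), inherits(dvf, "vector_field"))
  out <- landmarks
  out$out_of_grid <- logical(nrow(out))
  if (nrow(out) == 0L) return(out)
  p <- as.matrix(landmarks[, c("x_mm", "y_mm", "z_mm")])
  geom <- volume(array(0, dim = c(2, 2, 2)), spacing = dvf$spacing,
                 origin = dvf$origin, orientation = dvf$orientation)
  idx <- world_to_voxel(geom, p)
  disp <- interp_field(dvf, idx, fill = NA_real_)
  oog <- apply(is.na(disp), 1, any)
  disp[oog, ] <- 0
  p2 <- p + disp
  out$x_mm <- p2[, 1]; out$y_mm <- p2[, 2]; out$z_mm <- p2[, 3]
  out$out_of_grid <- oog
  out
}

#' Per-landmark 3-D Euclidean errors
#'
#' Distances in mm between matched landmarks (matched by `id`; the
#' tables must contain the same ids).
#'
#' @param predicted,truth Landmark data frames with matching ids.
#' @return Numeric vector of distances (mm), named by id.
#' @export
landmark_errors <- function(predicted, truth) {
  stopifnot(is.data.frame(predicted), is.data.frame(truth))
  if (nrow(predicted) != nrow(truth))
    stop("landmark lists have different lengths")
  m <- match(predicted$id, truth$id)
  if (any(is.na(m)))
    stop("landmark ids do not match between the two lists")
  tr <- truth[m, ]
  d <- sqrt((predicted$x_mm - tr$x_mm)^2 + (predicted$y_mm - tr$y_mm)^2 +
              (predicted$z_mm - tr$z_mm)^2)
  names(d) <- predicted$id
  d
}

#' Summarise landmark errors with optional outlier exclusion
#'
#' Mean and sample standard deviation (n - 1 denominator) of the
#' distances, optionally excluding distances above a hard cutoff
#' (e.g. the 5 mm rule used when separating gross registration failures
#' from the error distribution). Exclusion is opt-in and reported.
#'
#' @param distances Numeric vector of distances (mm), non-empty.
#' @param cutoff Exclusion threshold in mm, or `NULL` (default) for no
#'   exclusion.
#' @return An `error_summary`: list with `distances` (included), `mean`,
#'   `std`, `n_total`, `n_excluded`, `cutoff`.
#' @export
summarize_errors <- function(distances, cutoff = NULL) {
  distances <- as.numeric(distances)
  if (length(distances) == 0L) stop("no distances to summarise")
  if (is.null(cutoff)) {
    keep <- rep(TRUE, length(distances))
  } else {
    stopifnot(is.numeric(cutoff), length(cutoff) == 1L, cutoff > 0)
    keep <- distances <= cutoff
  }
  if (!any(keep)) stop("all distances excluded by the cutoff")
  inc <- distances[keep]
  structure(list(distances = inc,
                 mean = mean(inc),
                 std = if (length(inc) > 1L) stats::sd(inc) else NA_real_,
                 n_total = length(distances),
                 n_excluded = sum(!keep),
                 cutoff = if (is.null(cutoff)) NA_real_ else cutoff),
            class = "error_summary")
}

#' @export
print.error_summary <- function(x, ...) {
  cat(sprintf("<error_summary> %.3f +/- %.3f mm (n = %d, excluded %d%s)\n",
              x$mean, x$std, x$n_total - x$n_excluded, x$n_excluded,
              if (is.na(x$cutoff)) "" else sprintf(" at > %g mm", x$cutoff)))
  invisible(x)
}

#' Paired t-test between two matched error lists
#'
#' Two-sided paired t-test: `t = mean(a - b) / (sd(a - b) / sqrt(n))`
#' with `n - 1` degrees of freedom, as used to compare per-landmark
#' errors of two methods measured on the same landmark set.
#'
#' @param errors_a,errors_b Matched numeric vectors, length n >= 2.
#' @return List with `t_statistic`, `p_value`, `degrees_of_freedom`.
#' @export
paired_t_test <- function(errors_a, errors_b) {
  a <- as.numeric(errors_a); b <- as.numeric(errors_b)
  if (length(a) != length(b)) stop("error lists must be matched (equal length)")
  n <- length(a)
  if (n < 2L) stop("need at least 2 paired observations")
  d <- a - b
  s <- stats::sd(d)
  if (s == 0) stop("degenerate test: paired differences have zero variance")
  t <- mean(d) / (s / sqrt(n))
  list(t_statistic = t,
       p_value = 2 * stats::pt(-abs(t), df = n - 1),
       degrees_of_freedom = n - 1L)
}

#' Evaluate a registration with landmark pairs (TRE)
#'
#' The dataset's intended use: project the image-1 landmarks through a
#' registration's DVF and measure the 3-D distances to the matched
#' image-2 landmarks (the target registration error, TRE), summarised
#' with optional outlier exclusion.
#'
#' @param landmarks1,landmarks2 Matched landmark frames for image 1 and
#'   image 2 (same ids).
#' @param dvf A [vector_field()] mapping image-1 positions into image-2
#'   space, or `NULL` to evaluate the unregistered offsets.
#' @param cutoff Optional exclusion threshold in mm (default `NULL`).
#' @return An `error_summary`.
#' @export
evaluate_dir <- function(landmarks1, landmarks2, dvf = NULL, cutoff = NULL) {
  projected <- if (is.null(dvf)) landmarks1
               else project_landmarks_through_dvf(landmarks1, dvf)
  summarize_errors(landmark_errors(projected, landmarks2), cutoff = cutoff)
}
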