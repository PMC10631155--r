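#' Convert a mask to a point cloud of pixel centers
#'
#' Every foreground pixel contributes one point at its physical center,
#' `x = (col_0based + 0.5) * spacing_col`, `y = (row_0based + 0.5) * spacing_row`.
#' The covariance of this filled point cloud, not of the boundary, is what
#' the ellipse fit consumes.
#'
#' @param mask A [cross_section_mask()] with at least one foreground pixel.
#' @return A `point_cloud`: list with `points` (n x 2 matrix, columns x, y)
#'   and `n`.
#' @export
mask_to_point_cloud <- function(mask) {
  idx <- which(mask$grid, arr.ind = TRUE)
  if (nrow(idx) == 0L)
    abort_jshape("mask has no foreground pixels", "jshape_empty_region_error")
  sp <- mask$pixel_spacing_mm
  pts <- cbind(x = (idx[, 2] - 0.5) * sp[2],
               y = (idx[, 1] - 0.5) * sp[1])
  structure(list(points = pts, n = nrow(pts)), class = "point_cloud")
}

# Population (divide-by-n) covariance of a point cloud; the lamina-moment
# identities used by the analytic checks hold for this form, not for n - 1.
point_cloud_covariance <- function(cloud) {
  x <- cloud$points[, 1]; y <- cloud$points[, 2]; n <- cloud$n
  mx <- sum(x) / n; my <- sum(y) / n
  cxx <- sum((x - mx)^2) / n
  cyy <- sum((y - my)^2) / n
  cxy <- sum((x - mx) * (y - my)) / n
  list(center = c(x = mx, y = my),
       cov = matrix(c(cxx, cxy, cxy, cyy), 2, 2,
                    dimnames = list(c("x", "y"), c("x", "y"))))
}

#' Construct ellipse parameters directly
#'
#' Builds the same object [fit_ellipse()] returns, from explicit geometry.
#' Used by the phantom generator and anywhere a known ellipse must be
#' rasterized or tested for containment.
#'
#' @param center_mm Numeric pair (x, y), mm.
#' @param semi_major_mm,semi_minor_mm Positive semi-axis lengths, mm
#'   (major >= minor).
#' @param orientation_deg Angle of the major axis to the x-axis; stored
#'   normalized to [0, 180).
#' @return An `ellipse_fit` object.
#' @export
ellipse_params <- function(center_mm, semi_major_mm, semi_minor_mm,
                           orientation_deg = 0) {
  if (semi_minor_mm <= 0 || semi_major_mm < semi_minor_mm)
    abort_jshape("need semi_major_mm >= semi_minor_mm > 0", "jshape_type_error")
  structure(
    list(center = as.numeric(center_mm),
         semi_major_mm = semi_major_mm, semi_minor_mm = semi_minor_mm,
         orientation_deg = orientation_deg %% 180,
         aspect_ratio = semi_major_mm / semi_minor_mm,
         eigenvalues = c((semi_major_mm / 2)^2, (semi_minor_mm / 2)^2)),
    class = "ellipse_fit")
}

#' @export
print.ellipse_fit <- function(x, ...) {
  cat(sprintf("<ellipse_fit> center (%.2f, %.2f) mm, a = %.3f, b = %.3f mm, theta = %.2f deg, a/b = %.3f\n",
              x$center[1], x$center[2], x$semi_major_mm, x$semi_minor_mm,
              x$orientation_deg, x$aspect_ratio))
  invisible(x)
}

#' Fit the best-fitting ellipse to a point cloud
#'
#' Center is the centroid; the eigen-decomposition of the 2x2 population
#' covariance gives eigenvalues `lambda1 >= lambda2` (mm^2) and the
#' major-axis direction. Under the default `"eigen"` scaling the semi-axes
#' are `a = 2 sqrt(lambda1)`, `b = 2 sqrt(lambda2)` — exact for a uniformly
#' filled elliptical lamina, whose covariance eigenvalues are `a^2/4` and
#' `b^2/4`. The alternative `"area"` scaling rescales both axes so the
#' ellipse area `pi a b` equals `target_area_mm2` (usually the mask area);
#' the aspect ratio and orientation are unaffected.
#'
#' For a circular cloud (eigenvalues equal within 1e-9 relative tolerance)
#' the orientation is defined as 0. Eigenvalue ratios below 1e-6 signal a
#' near-collinear cloud and raise a degenerate-geometry error.
#'
#' @param cloud A `point_cloud` from [mask_to_point_cloud()], n >= 3.
#' @param scaling `"eigen"` (default) or `"area"`.
#' @param target_area_mm2 Required when `scaling = "area"`.
#' @return An `ellipse_fit` with fields `center`, `semi_major_mm`,
#'   `semi_minor_mm`, `orientation_deg` in [0, 180), `aspect_ratio`,
#'   `eigenvalues`.
#' @export
fit_ellipse <- function(cloud, scaling = c("eigen", "area"),
                        target_area_mm2 = NULL) {
  scaling <- match.arg(scaling)
  if (cloud$n < 3L)
    abort_jshape(sprintf("need at least 3 points to fit an ellipse, got %d",
                         cloud$n),
                 "jshape_insufficient_points_error")
  pc <- point_cloud_covariance(cloud)
  ev <- eigen(pc$cov, symmetric = TRUE)
  l1 <- ev$values[1]; l2 <- ev$values[2]
  if (l1 <= 0 || l2 / l1 < 1e-6)
    abort_jshape("point cloud is (near-)collinear; ellipse fit is degenerate",
                 "jshape_degenerate_geometry_error")
  theta <- if ((l1 - l2) <= 1e-9 * l1) 0 else
    (atan2(ev$vectors[2, 1], ev$vectors[1, 1]) * 180 / pi) %% 180
  a <- 2 * sqrt(l1); b <- 2 * sqrt(l2)
  if (scaling == "area") {
    if (is.null(target_area_mm2) || target_area_mm2 <= 0)
      abort_jshape("`target_area_mm2` must be supplied for area scaling",
                   "jshape_type_error")
    s <- sqrt(target_area_mm2 / (pi * a * b))
    a <- a * s; b <- b * s
  }
  structure(
    list(center = unname(pc$center), semi_major_mm = a, semi_minor_mm = b,
         orientation_deg = theta, aspect_ratio = a / b,
         eigenvalues = c(l1, l2)),
    class = "ellipse_fit")
}

#' Fit an ellipse straight from a mask
#'
#' Convenience wrapper: [mask_to_point_cloud()] then [fit_ellipse()]; with
#' `"area"` scaling the target area is the mask's foreground area.
#'
#' @inheritParams fit_ellipse
#' @param mask A [cross_section_mask()].
#' @return An `ellipse_fit`.
#' @export
fit_mask_ellipse <- function(mask, scaling = c("eigen", "area")) {
  scaling <- match.arg(scaling)
  cloud <- mask_to_point_cloud(mask)
  fit_ellipse(cloud, scaling,
              target_area_mm2 = cloud$n * pixel_area_mm2(mask))
}

#' Point-in-ellipse test
#'
#' The point is translated to the ellipse frame and rotated by minus the
#' orientation; it is inside iff `(u/a)^2 + (v/b)^2 <= 1` (closed region:
#' boundary points count as inside). Vectorized over points.
#'
#' @param e An `ellipse_fit`.
#' @param x,y Point coordinates in mm (equal-length vectors).
#' @return Logical vector.
#' @export
ellipse_contains <- function(e, x, y) {
  th <- e$orientation_deg * pi / 180
  ct <- cos(th); st <- sin(th)
  dx <- x - e$center[1]; dy <- y - e$center[2]
  u <- ct * dx + st * dy
  v <- -st * dx + ct * dy
  (u / e$semi_major_mm)^2 + (v / e$semi_minor_mm)^2 <= 1
}
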