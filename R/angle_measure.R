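#' Femoral anatomical axis from two landmarks
#'
#' @param proximal_mm,distal_mm Numeric triples (x, y, z) in the volume's
#'   physical coordinate system, mm. Must be distinct (separation > 1e-6 mm).
#' @return A `femur_axis` object.
#' @export
femur_axis <- function(proximal_mm, distal_mm) {
  proximal_mm <- as.numeric(proximal_mm); distal_mm <- as.numeric(distal_mm)
  if (length(proximal_mm) != 3L || length(distal_mm) != 3L)
    abort_jshape("landmarks must be (x, y, z) triples", "jshape_type_error")
  if (sqrt(sum((distal_mm - proximal_mm)^2)) <= 1e-6)
    abort_jshape("femur landmarks coincide; axis is undefined",
                 "jshape_degenerate_axis_error")
  structure(list(proximal_mm = proximal_mm, distal_mm = distal_mm),
            class = "femur_axis")
}

#' Imaging-plane normal vector
#'
#' Defaults to (0, 0, 1), the slice-stacking direction of a label volume:
#' the imaging plane is transverse by construction.
#'
#' @param vector Numeric triple; normalized to unit length.
#' @return A `plane_normal` object.
#' @export
plane_normal <- function(vector = c(0, 0, 1)) {
  vector <- as.numeric(vector)
  nrm <- sqrt(sum(vector^2))
  if (length(vector) != 3L || !is.finite(nrm) || nrm <= 1e-12)
    abort_jshape("plane normal must be a nonzero (x, y, z) triple",
                 "jshape_type_error")
  structure(list(vector = vector / nrm), class = "plane_normal")
}

#' Angle between the femoral axis and the imaging-plane normal
#'
#' The digital-goniometer measurement quantifying knee elevation:
#' `acos(|unit(distal - proximal) . normal|)` in degrees. Folding by the
#' absolute value maps the result into [0, 90] regardless of landmark order.
#'
#' @param axis A [femur_axis()].
#' @param normal A [plane_normal()]; defaults to the slice-axis direction.
#' @return Angle in degrees, in [0, 90].
#' @export
femur_plane_angle <- function(axis, normal = plane_normal()) {
  if (!inherits(axis, "femur_axis")) axis <- do.call(femur_axis, axis)
  if (!inherits(normal, "plane_normal")) normal <- plane_normal(normal)
  d <- axis$distal_mm - axis$proximal_mm
  u <- d / sqrt(sum(d^2))
  acos(min(1, abs(sum(u * normal$vector)))) * 180 / pi
}

#' Read a femur-landmark table
#'
#' CSV columns: `study`, `position`, `proximal_x/y/z`, `distal_x/y/z` (mm).
#'
#' @param path Path to the CSV file.
#' @return Data frame of landmarks.
#' @export
read_landmarks <- function(path) {
  if (!file.exists(path))
    abort_jshape(sprintf("no such landmark file '%s'", path), "jshape_io_error")
  lm <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("study", "position", "proximal_x", "proximal_y", "proximal_z",
            "distal_x", "distal_y", "distal_z")
  missing <- setdiff(need, names(lm))
  if (length(missing))
    abort_jshape(sprintf("landmark table lacks columns: %s",
                         paste(missing, collapse = ", ")),
                 "jshape_format_error")
  lm
}

#' Measure knee-elevation angles for a landmark table
#'
#' @param landmarks Data frame as returned by [read_landmarks()].
#' @param normal A [plane_normal()]; defaults to the slice axis.
#' @return The table with an `angle_deg` column appended.
#' @export
measure_angles <- function(landmarks, normal = plane_normal()) {
  landmarks$angle_deg <- vapply(seq_len(nrow(landmarks)), function(i) {
    ax <- femur_axis(
      c(landmarks$proximal_x[i], landmarks$proximal_y[i], landmarks$proximal_z[i]),
      c(landmarks$distal_x[i], landmarks$distal_y[i], landmarks$distal_z[i]))
    femur_plane_angle(ax, normal)
  }, 0)
  landmarks
}
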