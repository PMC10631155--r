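#' Rasterize an ellipse as a standalone mask
#'
#' Pixel-center rasterization under the same containment rule as
#' [rasterize_ellipse()], onto a freshly allocated grid.
#'
#' @param a_mm,b_mm Semi-axes in mm (major, minor; a >= b > 0).
#' @param orientation_deg Major-axis angle to the x-axis.
#' @param center_mm Numeric pair (x, y), mm.
#' @param grid_dim Integer pair (rows, cols).
#' @param pixel_spacing_mm Numeric pair (row, col) spacing, mm.
#' @param slice_index,muscle Carried into the returned mask.
#' @return A [cross_section_mask()]; may be empty (with a clipping warning)
#'   if the ellipse misses the grid.
#' @export
generate_ellipse_mask <- function(a_mm, b_mm, orientation_deg, center_mm,
                                  grid_dim, pixel_spacing_mm,
                                  slice_index = 0L, muscle = NA_character_) {
  if (a_mm <= 0 || b_mm <= 0)
    abort_jshape("semi-axes must be positive", "jshape_parameter_error")
  e <- ellipse_params(center_mm, max(a_mm, b_mm), min(a_mm, b_mm),
                      if (a_mm >= b_mm) orientation_deg
                      else orientation_deg + 90)
  template <- cross_section_mask(
    matrix(FALSE, grid_dim[1], grid_dim[2]), pixel_spacing_mm,
    slice_index = slice_index, muscle = muscle)
  rasterize_ellipse(e, template)
}

#' One-sided flattening of a cross-section (chordal truncation)
#'
#' Removes every foreground pixel whose y (pixel-center) coordinate lies
#' below `y_min + f * (y_max - y_min)`, cutting a D-shape into the lower
#' (posterior) side of the region. Models the surface-contact compression
#' of the posterior thigh in supine lying as a single-parameter family
#' whose J index demonstrably degrades as `f` grows; it is a truncation,
#' not a volume-preserving squash.
#'
#' @param mask A [cross_section_mask()].
#' @param f Flattening fraction in [0, 1); `f = 0` returns the mask
#'   unchanged.
#' @return The truncated mask.
#' @export
apply_flattening <- function(mask, f) {
  if (!is.finite(f) || f < 0 || f >= 1)
    abort_jshape("flattening fraction `f` must lie in [0, 1)",
                 "jshape_parameter_error")
  if (f == 0 || mask_pixel_count(mask) == 0L) return(mask)
  idx <- which(mask$grid, arr.ind = TRUE)
  y <- (idx[, 1] - 0.5) * mask$pixel_spacing_mm[1]
  cut <- min(y) + f * (max(y) - min(y))
  drop <- idx[y < cut, , drop = FALSE]
  grid <- mask$grid
  grid[drop] <- FALSE
  cross_section_mask(grid, mask$pixel_spacing_mm,
                     slice_index = mask$slice_index, muscle = mask$muscle)
}

# Flip pixels within one pixel of the region boundary with probability p.
# 4-neighborhood: a pixel is "boundary" if any 4-neighbor differs from it.
flip_boundary_pixels <- function(grid, p) {
  if (p <= 0) return(grid)
  nr <- nrow(grid); nc <- ncol(grid)
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- grid
  core <- pad[2:(nr + 1L), 2:(nc + 1L)]
  nb_diff <- (pad[1:nr, 2:(nc + 1L)] != core) |
             (pad[3:(nr + 2L), 2:(nc + 1L)] != core) |
             (pad[2:(nr + 1L), 1:nc] != core) |
             (pad[2:(nr + 1L), 3:(nc + 2L)] != core)
  cand <- which(nb_diff)
  if (!length(cand)) return(grid)
  flip <- cand[stats::runif(length(cand)) < p]
  grid[flip] <- !grid[flip]
  grid
}

#' Parametric description of one synthetic muscle
#'
#' Defines a near-elliptical muscle whose cross-section tapers smoothly
#' along its normalized length `s` in [0, 1]: both semi-axes are scaled by
#' `(4 s (1 - s))^axis_profile`, so the muscle belly (s = 0.5) has the base
#' axes and the ends are thinner. The center can drift linearly along the
#' length to mimic an oblique muscle path.
#'
#' @param name Muscle name.
#' @param label Unique positive integer label.
#' @param group `"hamstrings"` or `"quadriceps"` (selects the flattening
#'   schedule).
#' @param base_semi_axes_mm Numeric pair (a0, b0) at mid-length, a0 >= b0 > 0.
#' @param center_mm Numeric pair (x, y) at mid-length, mm.
#' @param orientation_deg Major-axis angle.
#' @param axis_profile Taper exponent (>= 0); 0 means no taper.
#' @param center_drift_mm Numeric pair: total (x, y) drift from the first
#'   to the last slice.
#' @return A `muscle_phantom_spec` object.
#' @export
muscle_phantom_spec <- function(name, label, group, base_semi_axes_mm,
                                center_mm, orientation_deg = 0,
                                axis_profile = 0.25,
                                center_drift_mm = c(0, 0)) {
  if (!group %in% c("hamstrings", "quadriceps"))
    abort_jshape("group must be 'hamstrings' or 'quadriceps'",
                 "jshape_parameter_error")
  a0 <- base_semi_axes_mm[1]; b0 <- base_semi_axes_mm[2]
  if (!(a0 >= b0 && b0 > 0))
    abort_jshape("need base semi-axes a0 >= b0 > 0", "jshape_parameter_error")
  if (axis_profile < 0)
    abort_jshape("axis_profile must be >= 0", "jshape_parameter_error")
  structure(
    list(name = name, label = as.integer(label), group = group,
         base_semi_axes_mm = as.numeric(base_semi_axes_mm),
         center_mm = as.numeric(center_mm),
         orientation_deg = orientation_deg,
         axis_profile = axis_profile,
         center_drift_mm = as.numeric(center_drift_mm)),
    class = "muscle_phantom_spec")
}

#' Full parametric description of a synthetic positioning study
#'
#' @param muscles List of [muscle_phantom_spec()] with unique labels.
#' @param flattening_by_position Named list: position name -> named list
#'   group -> flattening fraction in [0, 0.45]. The position order here is
#'   the study's condition order.
#' @param position_angles_deg Named numeric vector of nominal
#'   knee-elevation angles per position (same names).
#' @param grid Integer triple (n_slices, rows, cols).
#' @param pixel_spacing_mm In-plane (row, col) spacing, mm.
#' @param slice_thickness_mm Slice thickness, mm.
#' @param boundary_noise_sd_mm Segmentation-jitter scale; boundary pixels
#'   are flipped with probability `min(0.5, sd / (2 * mean(spacing)))`.
#'   0 disables noise.
#' @param seed Integer seed driving all randomness.
#' @return A `phantom_study_spec` object.
#' @export
phantom_study_spec <- function(muscles, flattening_by_position,
                               position_angles_deg,
                               grid = c(40L, 256L, 288L),
                               pixel_spacing_mm = c(0.65, 0.65),
                               slice_thickness_mm = 3.0,
                               boundary_noise_sd_mm = 0,
                               seed = 1L) {
  labels <- vapply(muscles, `[[`, 0L, "label")
  if (anyDuplicated(labels))
    abort_jshape("muscle labels must be unique", "jshape_parameter_error")
  for (pos in names(flattening_by_position)) {
    fs <- unlist(flattening_by_position[[pos]])
    if (any(fs < 0) || any(fs > 0.45))
      abort_jshape("flattening fractions must lie in [0, 0.45]",
                   "jshape_parameter_error")
  }
  if (!setequal(names(flattening_by_position), names(position_angles_deg)))
    abort_jshape("flattening and angle maps must cover the same positions",
                 "jshape_parameter_error")
  structure(
    list(muscles = muscles,
         flattening_by_position = flattening_by_position,
         position_angles_deg = position_angles_deg,
         grid = as.integer(grid),
         pixel_spacing_mm = as.numeric(pixel_spacing_mm),
         slice_thickness_mm = slice_thickness_mm,
         boundary_noise_sd_mm = boundary_noise_sd_mm,
         seed = as.integer(seed)),
    class = "phantom_study_spec")
}

#' Default synthetic three-position thigh study
#'
#' Seven muscles on a 256 x 288 grid at 0.65 x 0.65 mm in-plane spacing and
#' 3 mm slices (40 slices, 120 mm of thigh), matching a typical thigh MRI
#' acquisition. Hamstrings sit posteriorly (low y, the flattened side),
#' quadriceps anteriorly; base semi-axes are in the 10-26 mm range typical
#' of mid-thigh cross-sections. Flattening grows across positions for the
#' hamstrings (none 0.05, modest 0.15, high 0.30) and stays at 0.02 for the
#' quadriceps; nominal knee-elevation angles are high = 15, modest = 12,
#' none = 8 degrees. Boundary noise defaults to 0.3 mm of segmentation
#' jitter.
#'
#' @param seed Integer seed.
#' @param boundary_noise_sd_mm Override for the jitter scale.
#' @return A [phantom_study_spec()].
#' @export
default_phantom_spec <- function(seed = 1L, boundary_noise_sd_mm = 0.3) {
  muscles <- list(
    muscle_phantom_spec("biceps_femoris", 7L, "hamstrings",
                        c(21, 14), c(44, 36), orientation_deg = 15,
                        center_drift_mm = c(3, 2)),
    muscle_phantom_spec("semitendinosus", 6L, "hamstrings",
                        c(15, 10), c(94, 34), orientation_deg = 170,
                        center_drift_mm = c(-2, 2)),
    muscle_phantom_spec("semimembranosus", 5L, "hamstrings",
                        c(19, 13), c(144, 36), orientation_deg = 160,
                        center_drift_mm = c(-3, 2)),
    muscle_phantom_spec("vastus_lateralis", 1L, "quadriceps",
                        c(24, 16), c(40, 110), orientation_deg = 25,
                        center_drift_mm = c(2, -2)),
    muscle_phantom_spec("vastus_intermedius", 2L, "quadriceps",
                        c(26, 17), c(94, 106), orientation_deg = 0,
                        center_drift_mm = c(0, -2)),
    muscle_phantom_spec("vastus_medialis", 3L, "quadriceps",
                        c(22, 15), c(148, 110), orientation_deg = 155,
                        center_drift_mm = c(-2, -2)),
    muscle_phantom_spec("rectus_femoris", 4L, "quadriceps",
                        c(16, 10), c(94, 148), orientation_deg = 5,
                        center_drift_mm = c(0, 2)))
  phantom_study_spec(
    muscles = muscles,
    flattening_by_position = list(
      high   = list(hamstrings = 0.30, quadriceps = 0.02),
      modest = list(hamstrings = 0.15, quadriceps = 0.02),
      none   = list(hamstrings = 0.05, quadriceps = 0.02)),
    position_angles_deg = c(high = 15, modest = 12, none = 8),
    boundary_noise_sd_mm = boundary_noise_sd_mm,
    seed = seed)
}

#' Generate the label volumes of a synthetic positioning study
#'
#' For each position, each muscle's per-slice ellipse is rasterized,
#' truncated by the position/group flattening fraction, and optionally
#' perturbed by boundary-pixel flips. All randomness is driven by one
#' generator seeded from `spec$seed`, so identical specs yield
#' byte-identical volumes. The manifest records every generating parameter
#' per slice.
#'
#' @param spec A [phantom_study_spec()].
#' @return List with `volumes` (named list of [label_volume()], one per
#'   position) and `manifest` (list: the spec parameters plus a per-slice
#'   parameter table).
#' @export
generate_study <- function(spec) {
  if (!inherits(spec, "phantom_study_spec"))
    abort_jshape("`spec` must be a phantom_study_spec",
                 "jshape_parameter_error")
  set.seed(spec$seed)
  ns <- spec$grid[1]; nr <- spec$grid[2]; nc <- spec$grid[3]
  sp <- spec$pixel_spacing_mm
  p_flip <- min(0.5, spec$boundary_noise_sd_mm / (2 * mean(sp)))
  label_names <- stats::setNames(
    vapply(spec$muscles, `[[`, "", "name"),
    as.character(vapply(spec$muscles, `[[`, 0L, "label")))

  volumes <- list()
  slice_manifest <- list()
  for (pos in names(spec$flattening_by_position)) {
    fmap <- spec$flattening_by_position[[pos]]
    vox <- array(0L, dim = c(ns, nr, nc))
    for (m in spec$muscles) {
      f <- fmap[[m$group]]
      if (is.null(f))
        abort_jshape(sprintf("no flattening fraction for group '%s' in position '%s'",
                             m$group, pos),
                     "jshape_parameter_error")
      for (i in seq_len(ns)) {
        s <- (i - 0.5) / ns
        scale <- (4 * s * (1 - s))^m$axis_profile
        a <- m$base_semi_axes_mm[1] * scale
        b <- m$base_semi_axes_mm[2] * scale
        ctr <- m$center_mm + (s - 0.5) * m$center_drift_mm
        if (b < mean(sp)) next
        mask <- generate_ellipse_mask(a, b, m$orientation_deg, ctr,
                                      c(nr, nc), sp,
                                      slice_index = i - 1L, muscle = m$name)
        mask <- apply_flattening(mask, f)
        grid <- flip_boundary_pixels(mask$grid, p_flip)
        sl <- vox[i, , ]
        if (any(sl[grid] != 0L))
          abort_jshape(sprintf("muscle '%s' overlaps an earlier label on slice %d of position %s",
                               m$name, i - 1L, pos),
                       "jshape_overlap_error")
        sl[grid] <- m$label
        vox[i, , ] <- sl
        slice_manifest[[length(slice_manifest) + 1L]] <- data.frame(
          position = pos, muscle = m$name, slice_index = i - 1L,
          a_mm = a, b_mm = b, orientation_deg = m$orientation_deg,
          center_x_mm = ctr[1], center_y_mm = ctr[2], flattening = f)
      }
    }
    volumes[[pos]] <- label_volume(vox, sp, spec$slice_thickness_mm,
                                   label_names)
  }
  manifest <- list(
    seed = spec$seed, grid = spec$grid, pixel_spacing_mm = sp,
    slice_thickness_mm = spec$slice_thickness_mm,
    boundary_noise_sd_mm = spec$boundary_noise_sd_mm,
    boundary_flip_probability = p_flip,
    position_angles_deg = as.list(spec$position_angles_deg),
    flattening_by_position = spec$flattening_by_position,
    slices = do.call(rbind, slice_manifest))
  list(volumes = volumes, manifest = manifest)
}

#' Write a generated phantom study to disk
#'
#' One NIfTI label volume per position (`<position>.nii.gz`), the manifest
#' as `manifest.yaml`, and a ready-to-run `config.yaml` for [run_study()].
#'
#' @param study Result of [generate_study()].
#' @param spec The [phantom_study_spec()] that produced it.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_phantom_study <- function(study, spec, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (pos in names(study$volumes))
    write_label_volume(study$volumes[[pos]],
                       file.path(dir, paste0(pos, ".nii.gz")))
  man <- study$manifest
  man$slices <- lapply(seq_len(nrow(man$slices)),
                       function(i) as.list(man$slices[i, ]))
  yaml::write_yaml(man, file.path(dir, "manifest.yaml"))
  labels <- study$volumes[[1]]$label_names
  cfg <- list(
    positions = lapply(names(study$volumes), function(pos)
      list(name = pos,
           angle_deg = as.numeric(spec$position_angles_deg[[pos]]),
           volume = paste0(pos, ".nii.gz"))),
    labels = as.list(stats::setNames(as.character(labels), names(labels))),
    reference_position = "none",
    min_pixels = 10L)
  if (!"none" %in% names(study$volumes))
    cfg$reference_position <- names(study$volumes)[[length(study$volumes)]]
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  invisible(dir)
}
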