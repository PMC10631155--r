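#' Binary cross-section mask on a physical pixel grid
#'
#' The unit every shape computation consumes: one muscle's segmented
#' cross-section on a single transverse slice. Pixel indices are 0-based;
#' the physical center of pixel `(i, j)` (row, col) is at
#' `((j + 0.5) * spacing_col, (i + 0.5) * spacing_row)` in (x, y) mm, so
#' x grows with column and y with row.
#'
#' @param grid Logical matrix (rows, cols); `TRUE` marks foreground.
#' @param pixel_spacing_mm Numeric pair: in-plane (row, col) spacing in mm.
#' @param slice_index Non-negative integer, 0-based slice position.
#' @param muscle Muscle name, or `NA` when unknown.
#' @return A `cross_section_mask` object.
#' @export
cross_section_mask <- function(grid, pixel_spacing_mm, slice_index = 0L,
                               muscle = NA_character_) {
  if (is.numeric(grid)) grid <- grid != 0
  if (!is.logical(grid) || !is.matrix(grid))
    abort_jshape("`grid` must be a logical matrix", "jshape_type_error")
  pixel_spacing_mm <- as.numeric(pixel_spacing_mm)
  if (length(pixel_spacing_mm) != 2L || any(!is.finite(pixel_spacing_mm)) ||
      any(pixel_spacing_mm <= 0))
    abort_jshape("`pixel_spacing_mm` must be two strictly positive numbers",
                 "jshape_type_error")
  if (slice_index < 0)
    abort_jshape("`slice_index` must be non-negative", "jshape_type_error")
  structure(
    list(grid = grid, pixel_spacing_mm = pixel_spacing_mm,
         slice_index = as.integer(slice_index), muscle = as.character(muscle)),
    class = "cross_section_mask")
}

#' @export
print.cross_section_mask <- function(x, ...) {
  cat(sprintf("<cross_section_mask> %s slice %d: %dx%d px @ %.3gx%.3g mm, %d foreground\n",
              x$muscle, x$slice_index, nrow(x$grid), ncol(x$grid),
              x$pixel_spacing_mm[1], x$pixel_spacing_mm[2], sum(x$grid)))
  invisible(x)
}

#' Number of foreground pixels in a mask
#' @param mask A `cross_section_mask`.
#' @return Integer count.
#' @export
mask_pixel_count <- function(mask) sum(mask$grid)

#' Physical area of one pixel of a mask, in mm^2
#' @param mask A `cross_section_mask`.
#' @return Positive scalar.
#' @export
pixel_area_mm2 <- function(mask) prod(mask$pixel_spacing_mm)

#' Integer label volume of segmented muscles
#'
#' Holds a 3-D integer grid ordered (slice, row, col) — the first axis
#' always indexes transverse slices — together with in-plane pixel spacing,
#' slice thickness and the label -> muscle-name map. Voxel values absent
#' from `label_names` are treated as background (zeroed) with a warning.
#'
#' @param voxels 3-D integer array ordered (slice, row, col).
#' @param pixel_spacing_mm Numeric pair (row, col) spacing in mm.
#' @param slice_thickness_mm Positive scalar, mm.
#' @param label_names Named character vector mapping label integers
#'   (as names) to muscle names, e.g. `c("1" = "rectus_femoris")`.
#' @return A `label_volume` object.
#' @export
label_volume <- function(voxels, pixel_spacing_mm, slice_thickness_mm,
                         label_names) {
  if (length(dim(voxels)) != 3L || any(dim(voxels) < 1L))
    abort_jshape("`voxels` must be a 3-D array with all dimensions >= 1",
                 "jshape_type_error")
  pixel_spacing_mm <- as.numeric(pixel_spacing_mm)
  if (length(pixel_spacing_mm) != 2L || any(pixel_spacing_mm <= 0) ||
      slice_thickness_mm <= 0)
    abort_jshape("spacings and slice thickness must be strictly positive",
                 "jshape_type_error")
  if (length(label_names) == 0L || is.null(names(label_names)))
    abort_jshape("`label_names` must be a non-empty named vector",
                 "jshape_format_error")
  labels <- as.integer(names(label_names))
  if (any(is.na(labels)) || any(labels <= 0L) || anyDuplicated(labels))
    abort_jshape("label keys must be unique positive integers",
                 "jshape_format_error")
  storage.mode(voxels) <- "integer"
  present <- sort(unique(as.vector(voxels)))
  unknown <- setdiff(present[present != 0L], labels)
  if (length(unknown)) {
    warn_jshape(sprintf("voxel values not in label_names treated as background: %s",
                        paste(unknown, collapse = ", ")),
                "jshape_unknown_label_warning")
    voxels[voxels %in% unknown] <- 0L
  }
  structure(
    list(voxels = voxels, pixel_spacing_mm = pixel_spacing_mm,
         slice_thickness_mm = as.numeric(slice_thickness_mm),
         label_names = stats::setNames(as.character(label_names),
                                       as.character(labels))),
    class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<label_volume> %d slices of %dx%d px @ %.3gx%.3g mm, thickness %.3g mm, %d labels\n",
              d[1], d[2], d[3], x$pixel_spacing_mm[1], x$pixel_spacing_mm[2],
              x$slice_thickness_mm, length(x$label_names)))
  invisible(x)
}

#' Number of transverse slices in a label volume
#' @param volume A `label_volume`.
#' @return Integer.
#' @export
n_slices <- function(volume) dim(volume$voxels)[1]

#' Read a NIfTI label volume
#'
#' Reads an integer-valued NIfTI file (.nii or .nii.gz), reorients so the
#' internal first axis indexes transverse slices (the file's third axis),
#' and takes pixel spacing and slice thickness from the header. Voxel
#' values absent from `label_names` become background with a warning.
#'
#' @param path Path to a NIfTI file.
#' @param label_names Named character vector, label integer -> muscle name.
#' @return A [label_volume()].
#' @export
read_label_volume <- function(path, label_names) {
  if (!is.character(path) || length(path) != 1L || !nzchar(path) ||
      !file.exists(path))
    abort_jshape(sprintf("cannot read label volume: no such file '%s'", path),
                 "jshape_io_error")
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e)
                    abort_jshape(sprintf("failed to read '%s': %s", path,
                                         conditionMessage(e)),
                                 "jshape_io_error"))
  pd <- RNifti::pixdim(img)
  if (length(pd) < 3L || any(!is.finite(pd[1:3])) || any(pd[1:3] <= 0))
    abort_jshape(sprintf("'%s' has no usable spacing information in its header",
                         path),
                 "jshape_format_error")
  arr <- as.array(img)
  if (length(dim(arr)) == 4L && dim(arr)[4] == 1L)
    arr <- arr[, , , 1, drop = TRUE]
  if (length(dim(arr)) != 3L)
    abort_jshape(sprintf("'%s' is not a 3-D volume", path),
                 "jshape_format_error")
  # file axes are (x = col, y = row, z = slice); internal order is (slice, row, col)
  voxels <- aperm(round(arr), c(3, 2, 1))
  label_volume(voxels, pixel_spacing_mm = c(pd[2], pd[1]),
               slice_thickness_mm = pd[3], label_names = label_names)
}

#' Write a label volume to NIfTI
#'
#' Inverse of [read_label_volume()]: the internal (slice, row, col) grid is
#' stored with slices along the file's third axis and spacings in the header.
#'
#' @param volume A [label_volume()].
#' @param path Output path (.nii or .nii.gz).
#' @return `path`, invisibly.
#' @export
write_label_volume <- function(volume, path) {
  arr <- aperm(volume$voxels, c(3, 2, 1))
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(volume$pixel_spacing_mm[2],
                           volume$pixel_spacing_mm[1],
                           volume$slice_thickness_mm)
  tryCatch(RNifti::writeNifti(img, path, datatype = "int16"),
           error = function(e)
             abort_jshape(sprintf("failed to write '%s': %s", path,
                                  conditionMessage(e)),
                          "jshape_io_error"))
  invisible(path)
}

#' Extract one muscle's mask from one slice of a label volume
#'
#' @param volume A [label_volume()].
#' @param slice_index 0-based slice index.
#' @param label Positive integer label present in `volume$label_names`.
#' @return A [cross_section_mask()]; may have zero foreground pixels.
#' @export
extract_slice_mask <- function(volume, slice_index, label) {
  ns <- n_slices(volume)
  if (slice_index < 0 || slice_index >= ns)
    abort_jshape(sprintf("slice_index %d out of range [0, %d)", slice_index, ns),
                 "jshape_bounds_error")
  key <- as.character(as.integer(label))
  if (!key %in% names(volume$label_names))
    abort_jshape(sprintf("label %s not in label_names", key),
                 "jshape_key_error")
  grid <- volume$voxels[slice_index + 1L, , ] == as.integer(label)
  cross_section_mask(grid, volume$pixel_spacing_mm,
                     slice_index = slice_index,
                     muscle = volume$label_names[[key]])
}

#' Write a results table as CSV
#'
#' Numeric fields are rendered with at least 6 significant digits. When the
#' table has both a `j` and a `degenerate` column, degenerate slices get the
#' sentinel token `"degenerate"` in the `j` field.
#'
#' @param rows A data frame of per-slice or per-muscle records.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results_table <- function(rows, path) {
  if (!is.data.frame(rows))
    abort_jshape("`rows` must be a data frame", "jshape_type_error")
  out <- rows
  for (nm in names(out)) {
    if (is.numeric(out[[nm]]))
      out[[nm]] <- ifelse(is.na(out[[nm]]), "NA",
                          formatC(out[[nm]], digits = 7, format = "g"))
  }
  if (all(c("j", "degenerate") %in% names(rows)) && nrow(rows) > 0)
    out$j[which(rows$degenerate %in% TRUE)] <- "degenerate"
  ok <- tryCatch({
    suppressWarnings(
      utils::write.table(out, path, sep = ",", quote = FALSE,
                         row.names = FALSE, col.names = TRUE))
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok))
    abort_jshape(sprintf("cannot write results table to '%s': %s", path,
                         conditionMessage(ok)),
                 "jshape_io_error")
  invisible(path)
}

#' Read per-slice 2-D mask files from a directory
#'
#' Accepts one file per slice per muscle named `<muscle>_<slice>.png` (any
#' nonzero/over-half-intensity pixel is foreground) or `<muscle>_<slice>.csv`
#' (a 0/1 matrix without header). Spacing is not stored in these files and
#' must be supplied.
#'
#' @param dir Directory containing the mask files.
#' @param pixel_spacing_mm Numeric pair (row, col) spacing in mm.
#' @return List of [cross_section_mask()] objects, sorted by muscle then slice.
#' @export
read_mask_directory <- function(dir, pixel_spacing_mm) {
  if (!dir.exists(dir))
    abort_jshape(sprintf("no such directory '%s'", dir), "jshape_io_error")
  files <- list.files(dir, pattern = "^.+_[0-9]+\\.(png|csv)$")
  if (!length(files))
    abort_jshape(sprintf("no mask files (<muscle>_<slice>.png/.csv) in '%s'", dir),
                 "jshape_io_error")
  parts <- regmatches(files, regexec("^(.+)_([0-9]+)\\.(png|csv)$", files))
  masks <- lapply(parts, function(p) {
    fp <- file.path(dir, p[1])
    grid <- if (p[4] == "png") {
      im <- png::readPNG(fp)
      if (length(dim(im)) == 3L) im <- im[, , 1]
      im > 0.5
    } else {
      as.matrix(utils::read.csv(fp, header = FALSE)) != 0
    }
    cross_section_mask(grid, pixel_spacing_mm,
                       slice_index = as.integer(p[3]), muscle = p[2])
  })
  ord <- order(vapply(masks, `[[`, "", "muscle"),
               vapply(masks, `[[`, 0L, "slice_index"))
  masks[ord]
}

#' Assemble per-slice masks into a label volume
#'
#' @param masks List of [cross_section_mask()] objects sharing one grid shape
#'   and spacing.
#' @param label_names Named character vector, label integer -> muscle name;
#'   every mask's muscle must appear among the values.
#' @param slice_thickness_mm Positive scalar, mm.
#' @return A [label_volume()].
#' @export
masks_to_label_volume <- function(masks, label_names, slice_thickness_mm) {
  if (!length(masks))
    abort_jshape("`masks` is empty", "jshape_type_error")
  dims <- dim(masks[[1]]$grid)
  ns <- max(vapply(masks, `[[`, 0L, "slice_index")) + 1L
  vox <- array(0L, dim = c(ns, dims[1], dims[2]))
  lab_of <- stats::setNames(as.integer(names(label_names)),
                            as.character(label_names))
  for (m in masks) {
    if (!identical(dim(m$grid), dims))
      abort_jshape("all masks must share one grid shape", "jshape_format_error")
    if (!m$muscle %in% names(lab_of))
      abort_jshape(sprintf("muscle '%s' not in label_names", m$muscle),
                   "jshape_key_error")
    sl <- vox[m$slice_index + 1L, , ]
    if (any(sl[m$grid] != 0L))
      abort_jshape(sprintf("overlapping masks on slice %d", m$slice_index),
                   "jshape_overlap_error")
    sl[m$grid] <- lab_of[[m$muscle]]
    vox[m$slice_index + 1L, , ] <- sl
  }
  label_volume(vox, masks[[1]]$pixel_spacing_mm, slice_thickness_mm,
               label_names)
}
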