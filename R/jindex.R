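#' Rasterize an ellipse onto a mask's grid
#'
#' Foreground pixels are exactly those whose centers satisfy
#' [ellipse_contains()]; the grid shape and spacing are taken from the
#' template. If the ellipse's bounding box extends beyond the grid it is
#' clipped and a warning is logged.
#'
#' @param e An `ellipse_fit`.
#' @param template A [cross_section_mask()] defining grid shape and spacing.
#' @return A [cross_section_mask()] of the rasterized ellipse.
#' @export
rasterize_ellipse <- function(e, template) {
  nr <- nrow(template$grid); nc <- ncol(template$grid)
  sp <- template$pixel_spacing_mm
  th <- e$orientation_deg * pi / 180
  wx <- sqrt((e$semi_major_mm * cos(th))^2 + (e$semi_minor_mm * sin(th))^2)
  wy <- sqrt((e$semi_major_mm * sin(th))^2 + (e$semi_minor_mm * cos(th))^2)
  if (e$center[1] - wx < 0 || e$center[1] + wx > nc * sp[2] ||
      e$center[2] - wy < 0 || e$center[2] + wy > nr * sp[1])
    warn_jshape("ellipse extends beyond the grid and was clipped",
                "jshape_clipped_warning")
  xs <- (seq_len(nc) - 0.5) * sp[2]
  ys <- (seq_len(nr) - 0.5) * sp[1]
  grid <- ellipse_contains(e,
                           x = matrix(xs, nr, nc, byrow = TRUE),
                           y = matrix(ys, nr, nc))
  dim(grid) <- c(nr, nc)
  cross_section_mask(grid, sp, slice_index = template$slice_index,
                     muscle = template$muscle)
}

#' J index of a mask against a fitted ellipse
#'
#' The fitted ellipse is rasterized onto the mask's grid by pixel-center
#' membership; the J index is the shared area divided by the area belonging
#' to exactly one of the two regions (the symmetric difference):
#' `J = |A ∩ E| / |A Δ E|`. This is not the Jaccard index `|A ∩ E|/|A ∪ E|`;
#' the two are related by `J = Jaccard / (1 - Jaccard)`. Larger J means a
#' more elliptical cross-section. When the mask equals the rasterized
#' ellipse exactly the denominator is zero: the result is flagged
#' degenerate and `j` carries no numeric value.
#'
#' The pixel-counting identity `|A| + |E| = 2 |A ∩ E| + |A Δ E|` holds
#' exactly on every input.
#'
#' @param mask A non-empty [cross_section_mask()].
#' @param e An `ellipse_fit`, typically from [fit_mask_ellipse()].
#' @return A `j_index_result`: list with `intersection_mm2`, `sym_diff_mm2`,
#'   `j` (`NA` when degenerate), `mask_area_mm2`, `ellipse_area_mm2`
#'   (rasterized), `degenerate`.
#' @export
compute_j_index <- function(mask, e) {
  if (mask_pixel_count(mask) == 0L)
    abort_jshape("mask has no foreground pixels", "jshape_empty_region_error")
  egrid <- rasterize_ellipse(e, mask)$grid
  px <- pixel_area_mm2(mask)
  n_inter <- sum(mask$grid & egrid)
  n_sdiff <- sum(xor(mask$grid, egrid))
  degenerate <- n_sdiff == 0L
  structure(
    list(intersection_mm2 = n_inter * px,
         sym_diff_mm2 = n_sdiff * px,
         j = if (degenerate) NA_real_ else n_inter / n_sdiff,
         mask_area_mm2 = sum(mask$grid) * px,
         ellipse_area_mm2 = sum(egrid) * px,
         degenerate = degenerate),
    class = "j_index_result")
}

#' @export
print.j_index_result <- function(x, ...) {
  cat(sprintf("<j_index_result> J = %s (inter %.2f mm^2, sym diff %.2f mm^2%s)\n",
              if (x$degenerate) "degenerate" else sprintf("%.4f", x$j),
              x$intersection_mm2, x$sym_diff_mm2,
              if (x$degenerate) ", mask equals rasterized ellipse" else ""))
  invisible(x)
}

#' J index of a mask against its own covariance fit
#'
#' One-call convenience: fit the ellipse, then score the mask against it.
#'
#' @inheritParams fit_mask_ellipse
#' @return A `j_index_result`.
#' @export
mask_j_index <- function(mask, scaling = c("eigen", "area")) {
  compute_j_index(mask, fit_mask_ellipse(mask, scaling))
}
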