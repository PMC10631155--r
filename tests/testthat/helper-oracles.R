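# Independent oracles and fixture builders. These deliberately re-derive
# quantities by brute force (explicit loops, direct trigonometry) so the
# package's vectorized paths are checked against an independent route.

# Brute-force population covariance: enumerate foreground pixel centers with
# an explicit double loop (column-major, matching linear index order), then
# apply the moment formulas directly.
oracle_covariance <- function(mask) {
  nr <- nrow(mask$grid); nc <- ncol(mask$grid)
  sp <- mask$pixel_spacing_mm
  xs <- numeric(0); ys <- numeric(0)
  for (j in seq_len(nc)) {
    for (i in seq_len(nr)) {
      if (mask$grid[i, j]) {
        xs <- c(xs, (j - 0.5) * sp[2])
        ys <- c(ys, (i - 0.5) * sp[1])
      }
    }
  }
  n <- length(xs)
  mx <- sum(xs) / n; my <- sum(ys) / n
  list(n = n, center = c(mx, my),
       cov = matrix(c(sum((xs - mx)^2) / n, sum((xs - mx) * (ys - my)) / n,
                      sum((xs - mx) * (ys - my)) / n, sum((ys - my)^2) / n),
                    2, 2))
}

# Independent pixel-count overlap oracle: double loop over the grid, own
# containment arithmetic (squared terms written out, no shared helper).
oracle_j_counts <- function(mask, e) {
  nr <- nrow(mask$grid); nc <- ncol(mask$grid)
  sp <- mask$pixel_spacing_mm
  th <- e$orientation_deg * pi / 180
  n_inter <- 0L; n_sdiff <- 0L; n_ell <- 0L
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      x <- (j - 0.5) * sp[2]; y <- (i - 0.5) * sp[1]
      dx <- x - e$center[1]; dy <- y - e$center[2]
      u <- cos(th) * dx + sin(th) * dy
      v <- -sin(th) * dx + cos(th) * dy
      in_e <- (u / e$semi_major_mm)^2 + (v / e$semi_minor_mm)^2 <= 1
      in_m <- mask$grid[i, j]
      if (in_e) n_ell <- n_ell + 1L
      if (in_m && in_e) n_inter <- n_inter + 1L
      if (xor(in_m, in_e)) n_sdiff <- n_sdiff + 1L
    }
  }
  list(n_inter = n_inter, n_sdiff = n_sdiff, n_ellipse = n_ell)
}

# Rasterize a rotated rectangle (w x h mm, angle deg) by pixel centers.
rectangle_mask <- function(w, h, theta_deg, center, grid_dim, spacing = c(1, 1)) {
  th <- theta_deg * pi / 180
  g <- matrix(FALSE, grid_dim[1], grid_dim[2])
  for (i in seq_len(grid_dim[1])) {
    for (j in seq_len(grid_dim[2])) {
      dx <- (j - 0.5) * spacing[2] - center[1]
      dy <- (i - 0.5) * spacing[1] - center[2]
      u <- cos(th) * dx + sin(th) * dy
      v <- -sin(th) * dx + cos(th) * dy
      g[i, j] <- abs(u) <= w / 2 && abs(v) <= h / 2
    }
  }
  cross_section_mask(g, spacing)
}

disc_mask <- function(r, center = c(32, 32), grid_dim = c(64, 64),
                      spacing = c(1, 1)) {
  generate_ellipse_mask(r, r, 0, center, grid_dim, spacing)
}

# Irregular blob: union of a few seeded random ellipses, guaranteed non-empty.
random_blob_mask <- function(seed, grid_dim = c(64, 64), spacing = c(1, 1)) {
  set.seed(seed)
  g <- matrix(FALSE, grid_dim[1], grid_dim[2])
  for (k in seq_len(sample(2:3, 1))) {
    a <- runif(1, 8, 16); b <- runif(1, 5, a)
    ctr <- c(runif(1, 22, grid_dim[2] - 22), runif(1, 22, grid_dim[1] - 22))
    th <- runif(1, 0, 180)
    m <- suppressWarnings(
      generate_ellipse_mask(a, b, th, ctr, grid_dim, spacing))
    g <- g | m$grid
  }
  cross_section_mask(g, spacing)
}

# The standard overlap fixtures used by several suites.
overlap_fixtures <- function() {
  circ <- disc_mask(20, c(32, 32), c(64, 64))
  rect <- rectangle_mask(60, 30, 0, c(40, 40), c(80, 80))
  half <- apply_flattening(disc_mask(20, c(32, 32), c(64, 64)), 0.5)
  blobs <- lapply(101:103, random_blob_mask)
  c(list(circle = circ, rectangle = rect, half_disc = half), blobs)
}

# Reduced-resolution phantom spec for fast pipeline tests: same muscle
# layout as the default, coarser grid and fewer slices.
small_phantom_spec <- function(seed = 1L, boundary_noise_sd_mm = 0,
                               flattening = NULL) {
  spec <- default_phantom_spec(seed = seed,
                               boundary_noise_sd_mm = boundary_noise_sd_mm)
  phantom_study_spec(
    muscles = spec$muscles,
    flattening_by_position =
      if (is.null(flattening)) spec$flattening_by_position else flattening,
    position_angles_deg = spec$position_angles_deg,
    grid = c(10L, 128L, 144L),
    pixel_spacing_mm = c(1.3, 1.3),
    slice_thickness_mm = 3.0,
    boundary_noise_sd_mm = boundary_noise_sd_mm,
    seed = seed)
}
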