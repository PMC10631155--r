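test_that("point clouds use the pixel-center convention", {
  g <- matrix(FALSE, 4, 4); g[1, 1] <- TRUE
  pc <- mask_to_point_cloud(cross_section_mask(g, c(1, 1)))
  expect_equal(unname(pc$points[1, ]), c(0.5, 0.5))

  g2 <- matrix(FALSE, 4, 4); g2[1:2, 1:2] <- TRUE
  pc2 <- mask_to_point_cloud(cross_section_mask(g2, c(1, 1)))
  expect_identical(pc2$n, 4L)
  expect_equal(unname(colMeans(pc2$points)), c(1, 1))

  # anisotropic spacing scales coordinates per axis
  pc3 <- mask_to_point_cloud(cross_section_mask(g, c(3, 0.5)))
  expect_equal(unname(pc3$points[1, ]), c(0.25, 1.5))

  expect_error(mask_to_point_cloud(
    cross_section_mask(matrix(FALSE, 4, 4), c(1, 1))),
    class = "jshape_empty_region_error")
})

test_that("degenerate point clouds are rejected", {
  g <- matrix(FALSE, 8, 8); g[3, 2:3] <- TRUE
  expect_error(fit_mask_ellipse(cross_section_mask(g, c(1, 1))),
               class = "jshape_insufficient_points_error")
  g[3, 2:7] <- TRUE  # 6 collinear pixels
  expect_error(fit_mask_ellipse(cross_section_mask(g, c(1, 1))),
               class = "jshape_degenerate_geometry_error")
})

test_that("filled-disc fit recovers the radius via the lamina moments", {
  m <- disc_mask(20, c(32, 32), c(64, 64))
  e <- fit_mask_ellipse(m)
  # continuous lamina: lambda = r^2/4, so 2*sqrt(lambda) = r
  expect_equal(e$semi_major_mm, 20, tolerance = 0.02)
  expect_equal(e$semi_minor_mm, 20, tolerance = 0.02)
  expect_identical(e$orientation_deg, 0)  # circle tie-break
  expect_equal(unname(e$center), c(32, 32), tolerance = 1e-8)
})

test_that("filled-rectangle fits match the analytic moments, including rotation", {
  # axis-aligned 60 x 30 rectangle: lambda1 = w^2/12, a = w/sqrt(3)
  r0 <- rectangle_mask(60, 30, 0, c(40, 40), c(80, 80))
  e0 <- fit_mask_ellipse(r0)
  expect_equal(e0$aspect_ratio, 2.0, tolerance = 0.02)
  expect_equal(e0$semi_major_mm, 60 / sqrt(3), tolerance = 0.02)
  expect_lt(min(e0$orientation_deg, 180 - e0$orientation_deg), 2)

  r30 <- rectangle_mask(60, 30, 30, c(45, 45), c(90, 90))
  e30 <- fit_mask_ellipse(r30)
  expect_equal(e30$orientation_deg, 30, tolerance = 2 / 30)
  expect_equal(e30$aspect_ratio, 2.0, tolerance = 0.02)
})

test_that("fits are equivariant under rigid motions of the cloud", {
  m <- rectangle_mask(40, 22, 20, c(40, 40), c(80, 80))
  e <- fit_mask_ellipse(m)
  cloud <- mask_to_point_cloud(m)

  # whole-pixel translation
  shifted <- cloud
  shifted$points <- sweep(cloud$points, 2, c(5, -3), `+`)
  es <- fit_ellipse(shifted)
  expect_equal(unname(es$center), unname(e$center) + c(5, -3),
               tolerance = 1e-12)
  expect_equal(es$semi_major_mm, e$semi_major_mm, tolerance = 1e-12)
  expect_equal(es$semi_minor_mm, e$semi_minor_mm, tolerance = 1e-12)
  expect_equal(es$orientation_deg, e$orientation_deg, tolerance = 1e-9)

  # rotations shift the orientation mod 180 and preserve the axes
  for (phi in c(17, 50, 121)) {
    th <- phi * pi / 180
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    rot <- cloud
    rot$points <- cloud$points %*% t(R)
    er <- fit_ellipse(rot)
    expect_equal(er$semi_major_mm, e$semi_major_mm, tolerance = 1e-9)
    expect_equal(er$aspect_ratio, e$aspect_ratio, tolerance = 1e-9)
    d <- (er$orientation_deg - e$orientation_deg - phi) %% 180
    expect_lt(min(d, 180 - d), 1e-6)
  }
})

test_that("parameter recovery holds for generated ellipse masks >= 15 px", {
  cases <- expand.grid(axes = list(c(20, 15), c(26, 16), c(26, 20)),
                       th = c(0, 40, 135))
  for (k in seq_len(nrow(cases))) {
    a <- cases$axes[[k]][1]; b <- cases$axes[[k]][2]; th <- cases$th[k]
    m <- generate_ellipse_mask(a, b, th, c(40, 40), c(80, 80), c(1, 1))
    e <- fit_mask_ellipse(m)
    expect_equal(e$semi_major_mm, a, tolerance = 0.02)
    expect_equal(e$semi_minor_mm, b, tolerance = 0.02)
    d <- (e$orientation_deg - th) %% 180
    expect_lt(min(d, 180 - d), 2)
  }
})

test_that("area scaling makes the ellipse area equal the mask area", {
  m <- apply_flattening(disc_mask(18, c(32, 32), c(64, 64)), 0.3)
  e <- fit_mask_ellipse(m, scaling = "area")
  expect_equal(pi * e$semi_major_mm * e$semi_minor_mm,
               mask_pixel_count(m) * pixel_area_mm2(m), tolerance = 1e-12)
  # aspect ratio agrees with the default scaling
  e0 <- fit_mask_ellipse(m)
  expect_equal(e$aspect_ratio, e0$aspect_ratio, tolerance = 1e-12)
})

test_that("point-in-ellipse follows the closed-boundary convention", {
  e <- ellipse_params(c(10, 10), 5, 3, 0)
  expect_true(ellipse_contains(e, 10, 10))
  expect_true(ellipse_contains(e, 15, 10))   # major-axis tip, on the boundary
  expect_true(ellipse_contains(e, 10, 13))   # minor-axis tip
  expect_false(ellipse_contains(e, 15.001, 10))
  # rotation carries the containment region with the ellipse
  er <- ellipse_params(c(10, 10), 5, 3, 90)
  expect_true(ellipse_contains(er, 10, 14.9))
  expect_false(ellipse_contains(er, 14.9, 10))
})
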