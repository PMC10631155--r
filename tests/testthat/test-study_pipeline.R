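make_slice_df <- function(j, degenerate = rep(FALSE, length(j)),
                          pixels = rep(100L, length(j))) {
  data.frame(study = "S1", position = "none", muscle = "rectus_femoris",
             slice_index = seq_along(j) - 1L, mask_pixels = pixels,
             j = j, degenerate = degenerate)
}

test_that("per-muscle summaries use the sample SD and exclude degenerate slices", {
  s <- summarize_muscle(make_slice_df(c(1, 2, 3)), "rectus_femoris", "none")
  expect_equal(s$mean_j, 2); expect_equal(s$sd_j, 1)
  expect_identical(s$n_slices, 3L)

  one <- summarize_muscle(make_slice_df(2.5), "rectus_femoris", "none")
  expect_equal(one$mean_j, 2.5); expect_identical(one$sd_j, 0)

  mix <- summarize_muscle(make_slice_df(c(1, 2, NA), degenerate = c(F, F, T)),
                          "rectus_femoris", "none")
  expect_equal(mix$mean_j, 1.5)
  expect_identical(mix$n_slices, 2L)
  expect_identical(mix$n_degenerate, 1L)

  # min_pixels filter removes small slices before averaging
  filt <- summarize_muscle(make_slice_df(c(1, 9), pixels = c(100L, 5L)),
                           "rectus_femoris", "none", min_pixels = 10L)
  expect_equal(filt$mean_j, 1)

  expect_error(
    summarize_muscle(make_slice_df(c(1, 2))[0, ], "rectus_femoris", "none"),
    class = "jshape_empty_summary_error")
})

test_that("percentage change is the magnitude relative to the reference mean", {
  ref <- data.frame(muscle = "semitendinosus", position = "none",
                    n_slices = 10L, mean_j = 2.0, sd_j = 0.1, n_degenerate = 0L)
  oth <- ref; oth$position <- "high"; oth$mean_j <- 1.728
  pc <- percent_change(ref, oth)
  expect_equal(pc$percent_change, 13.6)
  expect_equal(pc$signed_change, -13.6)
  expect_equal(percent_change(ref, ref)$percent_change, 0)
  ref1 <- ref; ref1$mean_j <- 1; oth1 <- oth; oth1$mean_j <- 2
  expect_equal(percent_change(ref1, oth1)$percent_change, 100)

  bad <- oth; bad$muscle <- "biceps_femoris"
  expect_error(percent_change(ref, bad), class = "jshape_config_error")
  zero <- ref; zero$mean_j <- 0
  expect_error(percent_change(zero, oth), class = "jshape_degenerate_error")
})

test_that("invalid study configurations are rejected", {
  expect_error(study_config(reference_position = "sideways"),
               class = "jshape_config_error")
  expect_error(study_config(min_pixels = 0), class = "jshape_config_error")
  expect_error(
    study_config(label_names = c("1" = "rectus_femoris",
                                 "2" = "rectus_femoris")),
    class = "jshape_config_error")
})

test_that("run_study equals the composition extract -> fit -> J per slice", {
  spec <- small_phantom_spec(seed = 5)
  vols <- generate_study(spec)$volumes
  cfg <- study_config()
  res <- run_study(cfg, vols)

  sl <- res$slices
  some <- sl[sl$included & sl$position == "modest" &
               sl$muscle %in% c("biceps_femoris", "rectus_femoris"), ]
  expect_gt(nrow(some), 4)
  vol <- vols[["modest"]]
  lab_of <- stats::setNames(as.integer(names(vol$label_names)),
                            vol$label_names)
  for (k in seq_len(nrow(some))) {
    mask <- extract_slice_mask(vol, some$slice_index[k],
                               lab_of[[some$muscle[k]]])
    r <- mask_j_index(mask)
    expect_identical(some$j[k], r$j)
    expect_identical(some$intersection_mm2[k], r$intersection_mm2)
    expect_identical(some$sym_diff_mm2[k], r$sym_diff_mm2)
  }

  # summaries in the result table match summarize_muscle on the slice rows
  s <- res$summaries[res$summaries$position == "modest" &
                       res$summaries$muscle == "biceps_femoris", ]
  manual <- summarize_muscle(sl[sl$position == "modest", ],
                             "biceps_femoris", "modest", cfg$min_pixels)
  expect_equal(s$mean_j, manual$mean_j)
  expect_equal(s$sd_j, manual$sd_j)
})

test_that("identical flattening across positions yields near-zero percent changes", {
  flat <- list(high = list(hamstrings = 0.1, quadriceps = 0.1),
               modest = list(hamstrings = 0.1, quadriceps = 0.1),
               none = list(hamstrings = 0.1, quadriceps = 0.1))
  vols <- generate_study(small_phantom_spec(seed = 9, flattening = flat))$volumes
  res <- run_study(study_config(), vols)
  expect_true(all(res$comparisons$percent_change < 2))
})

test_that("a muscle absent from a position is reported, not fatal", {
  spec <- small_phantom_spec(seed = 2)
  vols <- generate_study(spec)$volumes
  # erase rectus femoris (label 4) from one position
  vols[["high"]]$voxels[vols[["high"]]$voxels == 4L] <- 0L
  res <- run_study(study_config(), vols)
  row <- res$summaries[res$summaries$position == "high" &
                         res$summaries$muscle == "rectus_femoris", ]
  expect_identical(row$n_slices, 0L)
  expect_true(is.na(row$mean_j))
  # no comparison row for the missing pair, others present
  expect_false(any(res$comparisons$muscle == "rectus_femoris" &
                     res$comparisons$position_b == "high"))
  expect_true(any(res$comparisons$muscle == "biceps_femoris"))
})

test_that("repeated runs write byte-identical tables", {
  spec <- small_phantom_spec(seed = 13, boundary_noise_sd_mm = 0.3)
  cfg <- study_config()
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  run_study(cfg, generate_study(spec)$volumes, out_dir = d1)
  run_study(cfg, generate_study(spec)$volumes, out_dir = d2)
  for (f in c("slices.csv", "summaries.csv", "comparisons.csv"))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
})

test_that("multi-subject studies add subject-mean and pooled aggregations", {
  v1 <- generate_study(small_phantom_spec(seed = 21))$volumes
  v2 <- generate_study(small_phantom_spec(seed = 22))$volumes
  res <- run_study(study_config(), list(P01 = v1, P02 = v2))
  sm <- res$summaries
  expect_setequal(unique(sm$study), c("P01", "P02", "ALL", "POOLED"))
  a <- sm[sm$study == "ALL" & sm$muscle == "semitendinosus" &
            sm$position == "none", ]
  per <- sm[sm$study %in% c("P01", "P02") & sm$muscle == "semitendinosus" &
              sm$position == "none", ]
  expect_equal(a$mean_j, mean(per$mean_j))
  expect_identical(a$n_slices, sum(per$n_slices))
  expect_true(any(res$comparisons$study == "ALL"))
  expect_true(any(res$comparisons$study == "POOLED"))
})

test_that("a phantom study written to disk runs from its own YAML config", {
  spec <- small_phantom_spec(seed = 4)
  study <- generate_study(spec)
  dir <- withr::local_tempdir()
  write_phantom_study(study, spec, dir)
  cfg <- read_study_config(file.path(dir, "config.yaml"))
  expect_s3_class(cfg, "study_config")
  expect_identical(cfg$reference_position, "none")
  inputs <- attr(cfg, "inputs")
  expect_setequal(names(inputs), c("high", "modest", "none"))
  res <- run_study(cfg, as.list(inputs))
  expect_gt(nrow(res$slices), 100)
  direct <- run_study(cfg, study$volumes)
  expect_equal(res$comparisons$percent_change,
               direct$comparisons$percent_change, tolerance = 1e-12)
})

test_that("missing position inputs are a configuration error", {
  vols <- generate_study(small_phantom_spec(seed = 6))$volumes
  expect_error(run_study(study_config(), vols[c("high", "modest")]),
               class = "jshape_config_error")
})
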