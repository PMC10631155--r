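#' Default label -> muscle-name map for the seven thigh muscles
#'
#' Quadriceps: vastus lateralis, vastus intermedius, vastus medialis,
#' rectus femoris. Hamstrings: semimembranosus, semitendinosus,
#' biceps femoris.
#'
#' @return Named character vector, label integer (as name) -> muscle name.
#' @export
default_label_names <- function() {
  c("1" = "vastus_lateralis", "2" = "vastus_intermedius",
    "3" = "vastus_medialis", "4" = "rectus_femoris",
    "5" = "semimembranosus", "6" = "semitendinosus",
    "7" = "biceps_femoris")
}

#' Study configuration
#'
#' Describes a positioning study: the ordered conditions with their nominal
#' knee-elevation angles, the label -> muscle map, which condition is the
#' reference for percentage changes, and the per-slice inclusion threshold.
#'
#' @param positions Data frame with columns `name` and `angle_deg`; the
#'   default encodes the three conditions high = 15, modest = 12,
#'   none = 8 degrees.
#' @param label_names Named character vector, label -> muscle name.
#' @param reference_position Name of the reference condition (default
#'   `"none"`, the no-elevation baseline).
#' @param min_pixels Slices with fewer foreground pixels are excluded from
#'   fitting and summaries (default 10; covariance fits on a handful of
#'   muscle-end pixels are meaningless).
#' @param ellipse_scaling `"eigen"` or `"area"`, see [fit_ellipse()].
#' @return A `study_config` object.
#' @export
study_config <- function(positions = data.frame(
                           name = c("high", "modest", "none"),
                           angle_deg = c(15, 12, 8)),
                         label_names = default_label_names(),
                         reference_position = "none",
                         min_pixels = 10L,
                         ellipse_scaling = c("eigen", "area")) {
  ellipse_scaling <- match.arg(ellipse_scaling)
  if (!all(c("name", "angle_deg") %in% names(positions)))
    abort_jshape("`positions` needs columns `name` and `angle_deg`",
                 "jshape_config_error")
  if (!reference_position %in% positions$name)
    abort_jshape(sprintf("reference_position '%s' is not among positions (%s)",
                         reference_position,
                         paste(positions$name, collapse = ", ")),
                 "jshape_config_error")
  if (anyDuplicated(label_names) || anyDuplicated(positions$name))
    abort_jshape("muscle and position names must be unique",
                 "jshape_config_error")
  if (min_pixels < 1)
    abort_jshape("`min_pixels` must be a positive integer",
                 "jshape_config_error")
  structure(
    list(positions = positions, label_names = label_names,
         reference_position = reference_position,
         min_pixels = as.integer(min_pixels),
         ellipse_scaling = ellipse_scaling),
    class = "study_config")
}

#' Read a study configuration (and input paths) from YAML
#'
#' Expected keys: `positions` (list of `{name, angle_deg, volume?}`),
#' `labels` (map label -> muscle), `reference_position`, and optionally
#' `min_pixels`, `ellipse_scaling`, `landmarks` (CSV path). When positions
#' carry `volume` paths the returned object has an `inputs` attribute,
#' a named vector position -> path, resolved relative to the YAML file.
#'
#' @param path Path to a YAML file.
#' @return A `study_config`; input paths, if present, in `attr(, "inputs")`.
#' @export
read_study_config <- function(path) {
  if (!file.exists(path))
    abort_jshape(sprintf("no such config file '%s'", path), "jshape_io_error")
  y <- yaml::read_yaml(path)
  pos <- do.call(rbind, lapply(y$positions, function(p)
    data.frame(name = p$name, angle_deg = as.numeric(p$angle_deg))))
  labels <- stats::setNames(as.character(unlist(y$labels)), names(y$labels))
  cfg <- study_config(
    positions = pos, label_names = labels,
    reference_position = y$reference_position,
    min_pixels = if (is.null(y$min_pixels)) 10L else y$min_pixels,
    ellipse_scaling = if (is.null(y$ellipse_scaling)) "eigen"
                      else y$ellipse_scaling)
  vols <- vapply(y$positions, function(p)
    if (is.null(p$volume)) NA_character_ else p$volume, "")
  if (!all(is.na(vols))) {
    rel <- !is.na(vols) & !grepl("^/", vols)
    vols[rel] <- file.path(dirname(path), vols[rel])
    attr(cfg, "inputs") <- stats::setNames(vols, pos$name)
  }
  if (!is.null(y$landmarks)) {
    lp <- if (grepl("^/", y$landmarks)) y$landmarks
          else file.path(dirname(path), y$landmarks)
    attr(cfg, "landmarks") <- lp
  }
  cfg
}

#' Summarize per-slice J indices for one muscle in one position
#'
#' Mean and sample (n - 1) standard deviation of `j` over slices passing
#' the `min_pixels` filter; degenerate slices are counted but excluded
#' from the mean. A single included slice yields sd 0.
#'
#' @param results Data frame of per-slice rows (as produced by
#'   [run_study()]) with columns `muscle`, `position`, `mask_pixels`, `j`,
#'   `degenerate`.
#' @param muscle,position Which subset to summarize.
#' @param min_pixels Inclusion threshold on foreground pixel count.
#' @return One-row data frame: `muscle`, `position`, `n_slices`, `mean_j`,
#'   `sd_j`, `n_degenerate`.
#' @export
summarize_muscle <- function(results, muscle, position, min_pixels = 10L) {
  sub <- results[results$muscle == muscle & results$position == position &
                   results$mask_pixels >= min_pixels, , drop = FALSE]
  deg <- sub$degenerate %in% TRUE
  j <- sub$j[!deg & !is.na(sub$j)]
  if (!length(j))
    abort_jshape(sprintf("no usable slices for %s in position %s",
                         muscle, position),
                 "jshape_empty_summary_error")
  data.frame(muscle = muscle, position = position,
             n_slices = length(j), mean_j = mean(j),
             sd_j = if (length(j) > 1L) stats::sd(j) else 0,
             n_degenerate = sum(deg))
}

#' Percentage change in mean J between two positions
#'
#' `|mean_j_other - mean_j_reference| / mean_j_reference * 100`, reported
#' as a magnitude; the signed change is retained alongside because shape
#' deviation can move in either direction across conditions.
#'
#' @param reference,other One-row summaries from [summarize_muscle()] for
#'   the same muscle.
#' @return One-row data frame: `muscle`, `position_a` (reference),
#'   `position_b`, `percent_change`, `signed_change`.
#' @export
percent_change <- function(reference, other) {
  if (!identical(reference$muscle, other$muscle))
    abort_jshape(sprintf("muscle mismatch: '%s' vs '%s'",
                         reference$muscle, other$muscle),
                 "jshape_config_error")
  if (!is.finite(reference$mean_j) || reference$mean_j <= 0)
    abort_jshape("reference mean J must be positive",
                 "jshape_degenerate_error")
  d <- other$mean_j - reference$mean_j
  data.frame(muscle = reference$muscle,
             position_a = reference$position, position_b = other$position,
             percent_change = abs(d) / reference$mean_j * 100,
             signed_change = d / reference$mean_j * 100)
}

# Per-slice rows for one subject x position volume.
slice_rows_for_volume <- function(volume, config, study, position) {
  rows <- list()
  for (key in names(volume$label_names)) {
    muscle <- volume$label_names[[key]]
    for (s in seq_len(n_slices(volume)) - 1L) {
      mask <- extract_slice_mask(volume, s, as.integer(key))
      npx <- mask_pixel_count(mask)
      if (npx == 0L) next
      included <- npx >= config$min_pixels
      row <- data.frame(
        study = study, position = position, muscle = muscle,
        slice_index = s, mask_pixels = npx,
        mask_area_mm2 = npx * pixel_area_mm2(mask),
        ellipse_area_mm2 = NA_real_, intersection_mm2 = NA_real_,
        sym_diff_mm2 = NA_real_, j = NA_real_, degenerate = NA,
        included = included)
      if (included) {
        res <- tryCatch(mask_j_index(mask, config$ellipse_scaling),
                        jshape_degenerate_geometry_error = function(e) NULL)
        if (is.null(res)) {
          row$included <- FALSE
        } else {
          row$ellipse_area_mm2 <- res$ellipse_area_mm2
          row$intersection_mm2 <- res$intersection_mm2
          row$sym_diff_mm2 <- res$sym_diff_mm2
          row$j <- res$j
          row$degenerate <- res$degenerate
        }
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  do.call(rbind, rows)
}

summary_row_or_missing <- function(slices, muscle, position, min_pixels,
                                   study) {
  out <- tryCatch(summarize_muscle(slices, muscle, position, min_pixels),
                  jshape_empty_summary_error = function(e)
                    data.frame(muscle = muscle, position = position,
                               n_slices = 0L, mean_j = NA_real_,
                               sd_j = NA_real_, n_degenerate = 0L))
  cbind(data.frame(study = study), out)
}

#' Run the full positioning study
#'
#' For every position, muscle and slice with at least `min_pixels`
#' foreground pixels: point cloud -> covariance ellipse fit -> J index.
#' Per-muscle summaries (mean +/- SD of J over included, non-degenerate
#' slices) are computed per subject, and every non-reference position is
#' compared against the reference by percentage change in mean J.
#'
#' With several subjects two aggregation readings are emitted alongside the
#' per-subject rows: `"ALL"` (unweighted mean of subject means; its `sd_j`
#' is the SD across subject means) and `"POOLED"` (all subjects' slices
#' pooled). For a single subject only its own rows appear.
#'
#' @param config A [study_config()].
#' @param inputs Either a named list/vector mapping position name ->
#'   [label_volume()] (or NIfTI path) for a single subject, or a named list
#'   of such lists, one per subject.
#' @param landmarks Optional landmark data frame (see [read_landmarks()]);
#'   knee-elevation angles are measured and returned.
#' @param out_dir Optional directory; when given, `slices.csv`,
#'   `summaries.csv`, `comparisons.csv` (and `angles.csv` if landmarks were
#'   supplied) are written there.
#' @return A `study_results` object: list with data frames `slices`,
#'   `summaries`, `comparisons`, optional `angles`, the `config`, and any
#'   collected `warnings`.
#' @export
run_study <- function(config, inputs, landmarks = NULL, out_dir = NULL) {
  if (!inherits(config, "study_config"))
    abort_jshape("`config` must be a study_config", "jshape_config_error")
  pos_names <- config$positions$name

  # normalize to subjects -> positions -> volume
  is_single <- length(inputs) && all(names(inputs) %in% pos_names)
  subjects <- if (is_single) list(S1 = inputs) else inputs
  if (is.null(names(subjects)) || any(!nzchar(names(subjects))))
    abort_jshape("subject inputs must be named", "jshape_config_error")
  for (sid in names(subjects)) {
    missing <- setdiff(pos_names, names(subjects[[sid]]))
    if (length(missing))
      abort_jshape(sprintf("subject %s lacks input for position(s): %s",
                           sid, paste(missing, collapse = ", ")),
                   "jshape_config_error")
  }

  warnings_log <- character()
  slices <- withCallingHandlers({
    sl <- list()
    for (sid in names(subjects)) {
      for (pos in pos_names) {
        vol <- subjects[[sid]][[pos]]
        if (is.character(vol))
          vol <- read_label_volume(vol, config$label_names)
        sl[[length(sl) + 1L]] <-
          slice_rows_for_volume(vol, config, sid, pos)
      }
    }
    do.call(rbind, sl)
  }, jshape_warning = function(w) {
    warnings_log <<- c(warnings_log, conditionMessage(w))
    invokeRestart("muffleWarning")
  })

  muscles <- unname(config$label_names)
  sids <- names(subjects)
  summaries <- do.call(rbind, lapply(sids, function(sid) {
    sub <- slices[slices$study == sid, , drop = FALSE]
    do.call(rbind, lapply(pos_names, function(pos)
      do.call(rbind, lapply(muscles, function(m)
        summary_row_or_missing(sub, m, pos, config$min_pixels, sid)))))
  }))

  if (length(sids) > 1L) {
    agg <- do.call(rbind, lapply(pos_names, function(pos)
      do.call(rbind, lapply(muscles, function(m) {
        per <- summaries[summaries$position == pos & summaries$muscle == m &
                           summaries$study %in% sids &
                           summaries$n_slices > 0, , drop = FALSE]
        all_row <- data.frame(
          study = "ALL", muscle = m, position = pos,
          n_slices = sum(per$n_slices),
          mean_j = if (nrow(per)) mean(per$mean_j) else NA_real_,
          sd_j = if (nrow(per) > 1L) stats::sd(per$mean_j) else 0,
          n_degenerate = sum(per$n_degenerate))
        pooled <- summary_row_or_missing(slices, m, pos, config$min_pixels,
                                         "POOLED")
        rbind(all_row, pooled)
      }))))
    summaries <- rbind(summaries, agg)
  }

  ref <- config$reference_position
  comp_groups <- unique(summaries$study)
  comparisons <- do.call(rbind, lapply(comp_groups, function(g) {
    sg <- summaries[summaries$study == g, , drop = FALSE]
    do.call(rbind, lapply(muscles, function(m) {
      r <- sg[sg$muscle == m & sg$position == ref, , drop = FALSE]
      if (nrow(r) != 1L || r$n_slices == 0L || !is.finite(r$mean_j) ||
          r$mean_j <= 0) return(NULL)
      do.call(rbind, lapply(setdiff(pos_names, ref), function(pos) {
        o <- sg[sg$muscle == m & sg$position == pos, , drop = FALSE]
        if (nrow(o) != 1L || o$n_slices == 0L) return(NULL)
        cbind(data.frame(study = g), percent_change(r, o))
      }))
    }))
  }))

  angles <- if (!is.null(landmarks)) measure_angles(landmarks) else NULL

  res <- structure(
    list(slices = slices, summaries = summaries, comparisons = comparisons,
         angles = angles, config = config, warnings = warnings_log),
    class = "study_results")

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    write_results_table(slices, file.path(out_dir, "slices.csv"))
    write_results_table(summaries, file.path(out_dir, "summaries.csv"))
    write_results_table(comparisons, file.path(out_dir, "comparisons.csv"))
    if (!is.null(angles))
      write_results_table(angles, file.path(out_dir, "angles.csv"))
  }
  res
}

#' @export
print.study_results <- function(x, ...) {
  cat(sprintf("<study_results> %d slice rows, %d summaries, %d comparisons, %d warnings\n",
              nrow(x$slices), nrow(x$summaries),
              if (is.null(x$comparisons)) 0L else nrow(x$comparisons),
              length(x$warnings)))
  invisible(x)
}
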