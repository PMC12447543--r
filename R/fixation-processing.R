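# Fixation report parsing, exclusion rules, and looking-time descriptives.
#
# Fixation data travel as a tidy data frame (class "fixation_report") with
# one row per fixation event and columns:
#   participant_id, age_group, trial_index, scene_id, index_in_trial,
#   x_px, y_px, duration_ms, started_at_center
# Coordinates are 0-based pixels, x = column, y = row, origin at the
# top-left of the image; real-valued coordinates are rounded half away from
# zero when mapped to pixels.

FIXATION_COLUMNS <- c("participant_id", "age_group", "trial_index",
                      "scene_id", "index_in_trial", "x_px", "y_px",
                      "duration_ms", "started_at_center")

new_fixation_report <- function(d) {
  d <- as.data.frame(d, stringsAsFactors = FALSE)
  rownames(d) <- NULL
  class(d) <- c("fixation_report", "data.frame")
  d
}

validate_fixations <- function(d) {
  miss <- setdiff(FIXATION_COLUMNS, names(d))
  if (length(miss) > 0L) {
    stopf("fixation report missing column(s): %s",
          paste(miss, collapse = ", "))
  }
  num <- c("trial_index", "index_in_trial", "x_px", "y_px", "duration_ms")
  for (col in num) {
    v <- suppressWarnings(as.numeric(d[[col]]))
    bad <- which(is.na(v) & !is.na(d[[col]]))
    if (length(bad) > 0L) {
      stopf("malformed numeric value in column '%s' at data row(s): %s",
            col, paste(utils::head(bad, 5L), collapse = ", "))
    }
    if (anyNA(v)) {
      stopf("missing value in column '%s' at data row(s): %s", col,
            paste(utils::head(which(is.na(v)), 5L), collapse = ", "))
    }
    d[[col]] <- v
  }
  if (any(d$duration_ms < 0)) stopf("negative fixation duration")
  d$started_at_center <- as.logical(d$started_at_center)
  if (anyNA(d$started_at_center)) stopf("malformed started_at_center value")
  # a trial is one scene viewing: the same (participant, trial_index) must
  # not map to two scenes
  key <- paste(d$participant_id, d$trial_index, sep = "\r")
  n_scene <- tapply(d$scene_id, key, function(s) length(unique(s)))
  if (any(n_scene > 1L)) {
    stopf("duplicate trial: participant/trial_index reused across scenes (%s)",
          sub("\r", " trial ", names(n_scene)[which(n_scene > 1L)[1L]]))
  }
  ord <- order(d$participant_id, d$trial_index, d$index_in_trial)
  new_fixation_report(d[ord, FIXATION_COLUMNS])
}

#' Read a tab-separated fixation event report
#'
#' Parses a fixation report with the documented columns (see
#' [write_fixation_report()] / the package README), validating types,
#' completeness, and trial uniqueness.
#'
#' @param path path to a tab-separated file with a header row.
#' @return A `"fixation_report"` data frame, one row per fixation, ordered
#'   by participant, trial, and fixation index.
#' @export
read_fixation_report <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (nrow(d) == 0L) stopf("empty fixation report: %s", path)
  validate_fixations(d)
}

#' @rdname read_fixation_report
#' @param fixations a `"fixation_report"` data frame to serialize.
#' @export
write_fixation_report <- function(fixations, path) {
  utils::write.table(fixations[, FIXATION_COLUMNS], path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Density map parameters
#'
#' @param image_h,image_w image size in pixels (the study display used
#'   1000 x 1000 scene images).
#' @param sigma_px standard deviation of the isotropic Gaussian smoothing
#'   kernel in pixels. The default 7.21 px corresponds to the -6 dB cutoff
#'   convention recorded in `cutoff_db`; the cutoff is metadata only and
#'   `sigma_px` is the operative parameter.
#' @param cutoff_db recorded cutoff frequency (dB); not used in computation.
#' @param drop_first_fixation drop the first fixation of each trial before
#'   accumulating the map (it is the trial-initial center fixation).
#' @return A list of class `"density_map_params"`.
#' @export
density_map_params <- function(image_h = 1000L, image_w = 1000L,
                               sigma_px = 7.21, cutoff_db = -6,
                               drop_first_fixation = TRUE) {
  stopifnot(sigma_px > 0, image_h >= 1L, image_w >= 1L)
  structure(list(image_h = as.integer(image_h),
                 image_w = as.integer(image_w),
                 sigma_px = sigma_px, cutoff_db = cutoff_db,
                 drop_first_fixation = isTRUE(drop_first_fixation)),
            class = "density_map_params")
}

# TRUE where the (rounded) fixation lands inside the image extent.
in_image <- function(x, y, params) {
  xi <- round_half_away(x)
  yi <- round_half_away(y)
  xi >= 0 & xi <= params$image_w - 1L & yi >= 0 & yi <= params$image_h - 1L
}

trial_keys <- function(d) paste(d$participant_id, d$trial_index, sep = "\r")

#' Apply trial-level exclusion rules
#'
#' Trials are excluded if (1) the trial did not start with the participant
#' looking at the screen center, (2) every fixation fell outside the image,
#' (3) the trial has fewer than three total fixations, or (4) the summed
#' fixation duration is below 1000 ms. Rules are evaluated in this order and
#' each excluded trial is attributed to the first rule it violates, so the
#' per-rule percentages are "of remaining trials" after earlier rules.
#'
#' @param fixations a `"fixation_report"` data frame.
#' @param params a [density_map_params()] object (supplies the image extent
#'   for the in-image test).
#' @return A list with `fixations` (the kept rows, same class) and `report`
#'   (class `"exclusion_report"`): per-trial outcomes plus a `summary`
#'   attribute with per-rule counts and sequential percentages.
#' @export
apply_trial_exclusions <- function(fixations, params = density_map_params()) {
  d <- validate_fixations(fixations)
  key <- trial_keys(d)
  trials <- split(seq_len(nrow(d)), key)
  rules <- c("center_start_fail", "outside_image_only", "lt3_fixations",
             "sum_dur_lt_1000ms")
  per_trial <- lapply(trials, function(idx) {
    t <- d[idx, ]
    rule <- NA_character_
    if (!t$started_at_center[1L]) {
      rule <- "center_start_fail"
    } else if (!any(in_image(t$x_px, t$y_px, params))) {
      rule <- "outside_image_only"
    } else if (nrow(t) < 3L) {
      rule <- "lt3_fixations"
    } else if (sum(t$duration_ms) < 1000) {
      rule <- "sum_dur_lt_1000ms"
    }
    data.frame(participant_id = t$participant_id[1L],
               trial_index = t$trial_index[1L],
               scene_id = t$scene_id[1L],
               rule = rule, kept = is.na(rule), stringsAsFactors = FALSE)
  })
  report <- do.call(rbind, per_trial)
  rownames(report) <- NULL
  # sequential percentages: each rule's denominator is the trials remaining
  # after the earlier rules
  remaining <- nrow(report)
  summ <- data.frame(rule = rules, n_excluded = 0L, pct_of_remaining = 0)
  for (i in seq_along(rules)) {
    n_i <- sum(report$rule == rules[i], na.rm = TRUE)
    summ$n_excluded[i] <- n_i
    summ$pct_of_remaining[i] <- if (remaining > 0) 100 * n_i / remaining else 0
    remaining <- remaining - n_i
  }
  attr(report, "summary") <- summ
  attr(report, "n_trials") <- nrow(report)
  attr(report, "n_kept") <- sum(report$kept)
  class(report) <- c("exclusion_report", "data.frame")
  kept_keys <- paste(report$participant_id[report$kept],
                     report$trial_index[report$kept], sep = "\r")
  kept <- new_fixation_report(d[key %in% kept_keys, ])
  list(fixations = kept, report = report)
}

#' Apply the subject-level usable-trial exclusion
#'
#' Removes participants who did not contribute at least `min_trials` usable
#' trials after trial-level exclusions.
#'
#' @param fixations a `"fixation_report"` of trials kept by
#'   [apply_trial_exclusions()].
#' @param min_trials minimum usable trials (default 18).
#' @return A list with `fixations` (kept rows) and `report`: a data frame of
#'   participants with usable-trial counts and a `kept` flag.
#' @export
apply_subject_exclusion <- function(fixations, min_trials = 18L) {
  d <- new_fixation_report(as.data.frame(fixations))
  key <- trial_keys(d)
  per_subj <- tapply(key, d$participant_id, function(k) length(unique(k)))
  report <- data.frame(participant_id = names(per_subj),
                       usable_trials = as.integer(per_subj),
                       kept = as.integer(per_subj) >= min_trials,
                       stringsAsFactors = FALSE)
  rownames(report) <- NULL
  if (!any(report$kept)) {
    warning("all participants removed by the usable-trial criterion",
            call. = FALSE)
  }
  kept <- new_fixation_report(
    d[d$participant_id %in% report$participant_id[report$kept], ])
  list(fixations = kept, report = report)
}

#' Per-group looking-time descriptives
#'
#' Computes, per age group, the across-participant mean and SD of: usable
#' trials contributed, fixations per trial, fixation duration (ms), and
#' total looking time per trial (ms). Each statistic is first computed per
#' participant, then summarized across participants, matching how such
#' descriptive tables are conventionally reported.
#'
#' @param fixations a `"fixation_report"` (after exclusions).
#' @return A data frame of class `"looking_stats"`, one row per age group.
#' @export
compute_looking_stats <- function(fixations) {
  d <- as.data.frame(fixations)
  if (nrow(d) == 0L) stopf("no fixation data")
  key <- trial_keys(d)
  per_subj <- lapply(split(d, d$participant_id), function(s) {
    tr <- split(s, trial_keys(s))
    data.frame(
      age_group = s$age_group[1L],
      n_trials = length(tr),
      fix_per_trial = mean(vapply(tr, nrow, 0L)),
      fix_duration = mean(s$duration_ms),
      total_look = mean(vapply(tr, function(t) sum(t$duration_ms), 0)),
      stringsAsFactors = FALSE
    )
  })
  ps <- do.call(rbind, per_subj)
  out <- do.call(rbind, lapply(split(ps, ps$age_group), function(g) {
    data.frame(
      age_group = g$age_group[1L], n = nrow(g),
      usable_trials_mean = mean(g$n_trials),
      usable_trials_sd = stats::sd(g$n_trials),
      fixations_per_trial_mean = mean(g$fix_per_trial),
      fixations_per_trial_sd = stats::sd(g$fix_per_trial),
      fixation_duration_mean = mean(g$fix_duration),
      fixation_duration_sd = stats::sd(g$fix_duration),
      total_look_mean = mean(g$total_look),
      total_look_sd = stats::sd(g$total_look),
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  class(out) <- c("looking_stats", "data.frame")
  out
}
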