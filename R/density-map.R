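# Fixation density maps.
#
# For each trial (one scene viewing) a matrix of zeros the size of the
# image accrues a count of 1 at the pixel of every countable fixation; the
# count image is smoothed with an isotropic Gaussian (sd = sigma_px,
# zero-padded boundary) and min-max rescaled to [0, 1] so 0 marks the least
# and 1 the most fixated pixel. The first fixation of each trial (the
# trial-initial center fixation) is dropped by default, and individual
# fixations falling outside the image are dropped from the map without
# excluding the trial.

# Accumulate integer fixation counts for one set of fixation rows.
fixation_count_matrix <- function(x_px, y_px, params,
                                  drop_first = params$drop_first_fixation) {
  if (drop_first && length(x_px) > 0L) {
    x_px <- x_px[-1L]
    y_px <- y_px[-1L]
  }
  keep <- in_image(x_px, y_px, params)
  x_px <- x_px[keep]
  y_px <- y_px[keep]
  if (length(x_px) == 0L) stopf("no countable fixations")
  m <- matrix(0, params$image_h, params$image_w)
  # x = column (0-based), y = row (0-based)
  idx <- cbind(round_half_away(y_px) + 1L, round_half_away(x_px) + 1L)
  for (i in seq_len(nrow(idx))) {
    m[idx[i, 1L], idx[i, 2L]] <- m[idx[i, 1L], idx[i, 2L]] + 1
  }
  m
}

# Min-max rescale to [0, 1]; a constant input is defined as all zeros.
mat2gray <- function(m) {
  lo <- min(m)
  hi <- max(m)
  if (hi == lo) return(matrix(0, nrow(m), ncol(m)))
  (m - lo) / (hi - lo)
}

#' Fixation density map for one trial
#'
#' @param trial rows of a `"fixation_report"` belonging to one trial
#'   (one participant x scene viewing), ordered by fixation index. Multiple
#'   trials of the same participant and scene may be passed together; their
#'   fixations are pooled (the first fixation of *each* trial is dropped).
#' @param params a [density_map_params()] object.
#' @return A matrix of class `"density_map"` with values in `[0, 1]` and
#'   attributes `participant_id`, `scene_id`, `n_fixations_counted`,
#'   `pre_normalization_mass` (smoothed mass before rescaling, equal to the
#'   number of countable fixations minus boundary truncation loss), and
#'   `params`.
#' @export
density_map <- function(trial, params = density_map_params()) {
  t <- as.data.frame(trial)
  if (nrow(t) == 0L) stopf("no countable fixations")
  counts <- matrix(0, params$image_h, params$image_w)
  n_counted <- 0L
  for (tr in split(t, trial_keys(t))) {
    tr <- tr[order(tr$index_in_trial), ]
    cm <- fixation_count_matrix(tr$x_px, tr$y_px, params)
    counts <- counts + cm
    n_counted <- n_counted + sum(cm)
  }
  sm <- smooth_gaussian(counts, params$sigma_px)
  structure(mat2gray(sm), class = c("density_map", "matrix"),
            participant_id = t$participant_id[1L],
            scene_id = t$scene_id[1L],
            n_fixations_counted = as.integer(n_counted),
            pre_normalization_mass = sum(sm),
            params = params)
}

#' Density maps for every participant x scene in a fixation report
#'
#' @param fixations a `"fixation_report"` (after exclusions).
#' @param params a [density_map_params()] object.
#' @return A nested list: `maps[[participant_id]][[scene_id]]` is a
#'   `"density_map"` matrix.
#' @export
density_maps <- function(fixations, params = density_map_params()) {
  d <- as.data.frame(fixations)
  lapply(split(d, d$participant_id), function(s) {
    lapply(split(s, s$scene_id), density_map, params = params)
  })
}

#' @export
print.density_map <- function(x, ...) {
  cat(sprintf(
    "Density map: participant %s, scene %s, %d x %d px, %d fixations\n",
    attr(x, "participant_id"), attr(x, "scene_id"), nrow(x), ncol(x),
    attr(x, "n_fixations_counted")))
  invisible(x)
}

#' Export a density map
#'
#' Writes the map either as an RDS binary array (compact) or as a portable
#' tab-separated text matrix.
#'
#' @param map a `"density_map"` matrix.
#' @param path output file path.
#' @param format `"rds"` or `"txt"`.
#' @export
export_density_map <- function(map, path, format = c("rds", "txt")) {
  format <- match.arg(format)
  if (format == "rds") {
    saveRDS(unclass(map), path)
  } else {
    write_text_matrix(unclass(map), path)
  }
  invisible(path)
}
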