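# Synthetic study generator.
#
# Generates complete studies with known ground truth: scenes carrying L
# levels of spatial structure ("abstraction levels" of increasing spatial
# scale), age groups whose fixation placement mixes those levels with known
# weights, and fMRI "subjects" whose ROI voxel patterns read out the same
# level structure through random orthogonal readouts plus noise. Every
# downstream stage of the pipeline is therefore testable against planted
# structure without any external download.

#' Generate multi-level synthetic scene features
#'
#' Each scene gets one non-negative spatial map per abstraction level and a
#' matching level embedding for voxel readout. A level map is an
#' exponentiated Gaussian-smoothed white-noise field, normalized to sum 1;
#' abstraction level is operationalized purely by the smoothing length
#' scale (strictly increasing with level). The level embedding is the
#' flattened block-mean down-sampling of the map on an
#' `embed_cells x embed_cells` grid.
#'
#' @param n_scenes number of scenes (>= 2).
#' @param H,W map size in pixels.
#' @param L number of abstraction levels.
#' @param smoothness length scales (pixels), one per level, strictly
#'   increasing with level.
#' @param contrast per-level field contrast: the smoothed unit-variance
#'   field is multiplied by this before exponentiation, so larger values
#'   give sparser, peakier maps. Defaults decrease with level (fine-scale
#'   salient features are sparse and high-contrast; abstract structure is
#'   diffuse), which also keeps the levels comparably recoverable from
#'   small numbers of fixations.
#' @param embed_cells embedding grid side; embedding dimension is
#'   `embed_cells^2`.
#' @param seed integer seed; output is a pure function of the arguments.
#' @return A list of `"scene_features"` objects with fields `scene_id`,
#'   `level_maps` (list of L `H x W` matrices, each summing to 1) and
#'   `level_embeddings` (list of L numeric vectors of length
#'   `embed_cells^2`).
#' @export
make_scene_features <- function(n_scenes, H = 64L, W = 64L, L = 3L,
                                smoothness = c(3, 8, 20),
                                contrast = c(2, 1, 0.8),
                                embed_cells = 8L, seed = 1L) {
  if (n_scenes < 2L) stopf("need at least 2 scenes")
  if (length(smoothness) != L) stopf("need one length scale per level")
  if (length(contrast) != L) stopf("need one contrast value per level")
  if (any(contrast <= 0)) stopf("contrast must be positive")
  if (any(diff(smoothness) <= 0)) {
    stopf("levels must increase in abstraction scale")
  }
  if (H %% embed_cells != 0L || W %% embed_cells != 0L) {
    stopf("H and W must be multiples of embed_cells")
  }
  ids <- sprintf("scene%03d", seq_len(n_scenes))
  with_seed(seed, {
    lapply(seq_len(n_scenes), function(s) {
      maps <- lapply(seq_len(L), function(l) {
        z <- smooth_gaussian(matrix(stats::rnorm(H * W), H, W),
                             smoothness[l])
        z <- (z - mean(z)) / stats::sd(z)
        m <- exp(contrast[l] * z)
        m / sum(m)
      })
      emb <- lapply(maps, block_mean_embedding, cells = embed_cells)
      structure(list(scene_id = ids[s], level_maps = maps,
                     level_embeddings = emb),
                class = "scene_features", H = H, W = W, L = L,
                D = embed_cells^2L)
    })
  })
}

# Flattened block means of a map on a cells x cells grid.
block_mean_embedding <- function(m, cells) {
  bh <- nrow(m) %/% cells
  bw <- ncol(m) %/% cells
  e <- matrix(0, cells, cells)
  for (i in seq_len(cells)) {
    for (j in seq_len(cells)) {
      e[i, j] <- mean(m[((i - 1L) * bh + 1L):(i * bh),
                        ((j - 1L) * bw + 1L):(j * bw)])
    }
  }
  as.vector(e)
}

#' Age group simulation profile
#'
#' Describes one simulated viewing population: how strongly its gaze is
#' driven by each scene abstraction level, and its basic looking
#' characteristics. Defaults for counts and durations follow the looking
#' statistics of free-viewing studies of infants and adults (about 9
#' fixations of ~440 ms per 5 s trial in infancy, ~16 fixations of ~300 ms
#' in adults).
#'
#' @param name one of `"young"`, `"old"`, `"adult"`.
#' @param mixture_weights non-negative weights over the L scene levels,
#'   summing to 1: fixation locations are sampled from the weighted mixture
#'   of the scene's level maps.
#' @param n_participants participants in this group.
#' @param trials_per_participant scene-viewing trials per participant.
#' @param fixations_per_trial_mean Poisson mean of per-trial fixation counts
#'   (excluding the prepended trial-initial center fixation).
#' @param fixation_duration_mean_ms mean of the log-normal fixation duration
#'   distribution, ms.
#' @param duration_sdlog log-scale sd of the duration distribution.
#' @param center_start_fail_rate,outside_only_rate per-trial probabilities
#'   of the two artifact modes the trial-level exclusion rules target:
#'   not starting at the screen center, and looking only off-image.
#' @return A list of class `"age_group_profile"`. The implied mean total
#'   looking time per trial is exposed as `total_look_ms_mean`.
#' @export
age_group_profile <- function(name, mixture_weights,
                              n_participants,
                              trials_per_participant = 50L,
                              fixations_per_trial_mean = 9.14,
                              fixation_duration_mean_ms = 443.63,
                              duration_sdlog = 0.4,
                              center_start_fail_rate = 0.022,
                              outside_only_rate = 0.0037) {
  if (any(mixture_weights < 0)) stopf("mixture weights must be >= 0")
  if (abs(sum(mixture_weights) - 1) > 1e-9) {
    stopf("mixture weights must sum to 1")
  }
  stopifnot(n_participants >= 0, trials_per_participant >= 1,
            fixations_per_trial_mean > 0, fixation_duration_mean_ms > 0)
  structure(list(
    name = name, mixture_weights = mixture_weights,
    n_participants = as.integer(n_participants),
    trials_per_participant = as.integer(trials_per_participant),
    fixations_per_trial_mean = fixations_per_trial_mean,
    fixation_duration_mean_ms = fixation_duration_mean_ms,
    duration_sdlog = duration_sdlog,
    total_look_ms_mean = fixations_per_trial_mean *
      fixation_duration_mean_ms,
    center_start_fail_rate = center_start_fail_rate,
    outside_only_rate = outside_only_rate
  ), class = "age_group_profile")
}

#' Synthetic ROI profile
#'
#' @param roi_id region identifier.
#' @param level_loadings weights over the L scene levels: the ROI's voxel
#'   patterns read out the level embeddings scaled by these loadings.
#' @param n_voxels voxels in the region (must exceed the embedding
#'   dimension so an orthogonal readout exists).
#' @param noise_sd sd of the Gaussian measurement noise added per voxel;
#'   the noise-free signal is scaled to unit root-mean-square pattern norm.
#' @return A list of class `"roi_profile"`.
#' @export
roi_profile <- function(roi_id, level_loadings, n_voxels = 200L,
                        noise_sd = 0.05) {
  stopifnot(n_voxels >= 2L, noise_sd >= 0)
  structure(list(roi_id = roi_id, level_loadings = level_loadings,
                 n_voxels = as.integer(n_voxels), noise_sd = noise_sd),
            class = "roi_profile")
}

#' Simulate the fixations of one trial
#'
#' Fixation locations are i.i.d. samples from the pixel distribution
#' proportional to the mixture of the scene's level maps under the
#' profile's weights, with sub-pixel uniform jitter. A trial-initial center
#' fixation is prepended (it is the one later dropped by density-map
#' construction). Durations are log-normal with the profile's mean.
#'
#' @param scene a `"scene_features"` object.
#' @param profile an [age_group_profile()].
#' @param n_fix number of fixations after the initial center fixation
#'   (>= 0).
#' @param seed integer seed.
#' @param participant_id,trial_index identifiers stamped on the rows.
#' @return A `"fixation_report"` data frame of `n_fix + 1` rows.
#' @export
simulate_fixations <- function(scene, profile, n_fix, seed,
                               participant_id = "p1", trial_index = 1L) {
  stopifnot(n_fix >= 0)
  H <- attr(scene, "H")
  W <- attr(scene, "W")
  w <- profile$mixture_weights
  if (length(w) != length(scene$level_maps)) {
    stopf("profile has %d weights but scene has %d levels", length(w),
          length(scene$level_maps))
  }
  mix <- Reduce(`+`, Map(`*`, w, scene$level_maps))
  if (sum(mix) <= 0) stopf("mixture collapses to an all-zero map")
  with_seed(seed, {
    idx <- if (n_fix > 0L) {
      sample.int(H * W, n_fix, replace = TRUE, prob = as.vector(mix))
    } else {
      integer(0)
    }
    # column-major index -> (row, col), 0-based, with sub-pixel jitter that
    # never crosses a pixel boundary under round-half-away rounding
    row0 <- (idx - 1L) %% H
    col0 <- (idx - 1L) %/% H
    jx <- stats::runif(n_fix, -0.499, 0.499)
    jy <- stats::runif(n_fix, -0.499, 0.499)
    mu_log <- log(profile$fixation_duration_mean_ms) -
      profile$duration_sdlog^2 / 2
    dur <- stats::rlnorm(n_fix + 1L, mu_log, profile$duration_sdlog)
    new_fixation_report(data.frame(
      participant_id = participant_id, age_group = profile$name,
      trial_index = trial_index, scene_id = scene$scene_id,
      index_in_trial = 0:n_fix,
      x_px = c((W - 1) / 2, col0 + jx),
      y_px = c((H - 1) / 2, row0 + jy),
      duration_ms = dur, started_at_center = TRUE,
      stringsAsFactors = FALSE
    ))
  })
}

# Random readout basis: D rows, orthonormal, each orthogonal to the
# constant vector. Requires n_voxels >= D + 1. Because the basis preserves
# inner products and maps onto mean-zero voxel profiles, the Pearson RSM of
# the noise-free patterns equals the Pearson RSM of the level embeddings
# exactly.
readout_basis <- function(D, n_voxels, seed) {
  if (n_voxels < D + 1L) {
    stopf("n_voxels must be at least embedding dimension + 1 (%d)", D + 1L)
  }
  with_seed(seed, {
    m <- matrix(stats::rnorm(D * n_voxels), D, n_voxels)
    m <- m - rowMeans(m)
    t(qr.Q(qr(t(m))))
  })
}

#' Simulate voxel activation patterns for one fMRI subject and ROI
#'
#' Each level's scene embeddings are row-centred, scaled to unit
#' root-mean-square norm, passed through a subject-specific random
#' orthogonal readout, weighted by the ROI's level loadings, summed, and
#' perturbed with Gaussian noise. Different `fmri_subject_seed`s give
#' different voxel readouts of the *same* representational geometry.
#'
#' @param scenes list of `"scene_features"` (>= 2 scenes).
#' @param roi an [roi_profile()].
#' @param fmri_subject_seed integer seed identifying the simulated subject.
#' @return A `"voxel_patterns"` object (scenes x voxels).
#' @export
simulate_voxel_patterns <- function(scenes, roi, fmri_subject_seed) {
  if (length(scenes) < 2L) stopf("need at least 2 scenes")
  D <- attr(scenes[[1L]], "D")
  L <- attr(scenes[[1L]], "L")
  if (length(roi$level_loadings) != L) {
    stopf("roi has %d loadings but scenes have %d levels",
          length(roi$level_loadings), L)
  }
  ids <- vapply(scenes, `[[`, "", "scene_id")
  signal <- matrix(0, length(scenes), roi$n_voxels)
  for (l in seq_len(L)) {
    if (roi$level_loadings[l] == 0) next
    E <- do.call(rbind, lapply(scenes, function(s) s$level_embeddings[[l]]))
    E <- E - rowMeans(E)
    E <- E / sqrt(mean(rowSums(E^2)))
    A <- readout_basis(D, roi$n_voxels,
                       derive_seed(fmri_subject_seed,
                                   paste0(roi$roi_id, ":level", l)))
    signal <- signal + roi$level_loadings[l] * (E %*% A)
  }
  noise <- with_seed(
    derive_seed(fmri_subject_seed, paste0(roi$roi_id, ":noise")),
    matrix(stats::rnorm(length(signal), sd = roi$noise_sd),
           nrow(signal), ncol(signal))
  )
  voxel_patterns(signal + noise, ids, roi$roi_id,
                 sprintf("fmri%02d", fmri_subject_seed))
}

#' Synthetic study configuration
#'
#' Bundles every generator parameter with known ground truth. The defaults
#' follow the design of a developmental scene-viewing study: 78 scenes, 50
#' trials per participant, two infant groups plus adults with realistic
#' fixation counts and durations, and 8 fMRI subjects. Gaze in the young
#' group is driven purely by the lowest (finest-scale) level; the old and
#' adult groups mix in progressively more abstract levels.
#'
#' @param n_scenes,H,W,L,smoothness,contrast,embed_cells scene parameters,
#'   as in [make_scene_features()].
#' @param profiles list of [age_group_profile()] objects.
#' @param rois list of [roi_profile()] objects.
#' @param n_fmri_subjects number of simulated fMRI subjects (default 8).
#' @param seed master seed; all randomness derives from it.
#' @return A list of class `"study_config"`.
#' @export
study_config <- function(n_scenes = 78L, H = 64L, W = 64L, L = 3L,
                         smoothness = c(3, 8, 20),
                         contrast = c(2, 1, 0.8), embed_cells = 8L,
                         profiles = NULL, rois = NULL,
                         n_fmri_subjects = 8L, seed = 1L) {
  if (is.null(profiles)) {
    profiles <- list(
      age_group_profile("young", c(1, 0, 0), 47L,
                        fixations_per_trial_mean = 9.14,
                        fixation_duration_mean_ms = 443.63),
      age_group_profile("old", c(0.5, 0.5, 0), 46L,
                        fixations_per_trial_mean = 9.50,
                        fixation_duration_mean_ms = 435.13),
      age_group_profile("adult", c(0.45, 0.45, 0.1), 45L,
                        fixations_per_trial_mean = 15.96,
                        fixation_duration_mean_ms = 297.38,
                        center_start_fail_rate = 0,
                        outside_only_rate = 0)
    )
  }
  if (is.null(rois)) {
    rois <- list(
      roi_profile("roi_low", c(1, 0, 0)),
      roi_profile("roi_mid", c(0, 1, 0)),
      roi_profile("roi_high", c(0, 0, 1))
    )
  }
  if (sum(vapply(profiles, `[[`, 0L, "n_participants")) == 0L) {
    stopf("config must include at least one participant")
  }
  structure(list(n_scenes = as.integer(n_scenes), H = as.integer(H),
                 W = as.integer(W), L = as.integer(L),
                 smoothness = smoothness, contrast = contrast,
                 embed_cells = as.integer(embed_cells),
                 profiles = profiles, rois = rois,
                 n_fmri_subjects = as.integer(n_fmri_subjects),
                 seed = as.integer(seed)),
            class = "study_config")
}

#' Reduced-scale demonstration configuration
#'
#' A small study (30 scenes, 20 participants per group, 64 x 64 maps, 200
#' voxels) that runs end to end in seconds and is used throughout the test
#' suite. Ground-truth structure matches [study_config()] defaults.
#'
#' @param seed master seed.
#' @param n_per_group participants per age group.
#' @param n_scenes number of scenes.
#' @return A `"study_config"`.
#' @export
demo_config <- function(seed = 1L, n_per_group = 20L, n_scenes = 30L) {
  study_config(
    n_scenes = n_scenes,
    profiles = list(
      age_group_profile("young", c(1, 0, 0), n_per_group,
                        trials_per_participant = n_scenes,
                        fixations_per_trial_mean = 9.14,
                        fixation_duration_mean_ms = 443.63),
      age_group_profile("old", c(0.5, 0.5, 0), n_per_group,
                        trials_per_participant = n_scenes,
                        fixations_per_trial_mean = 9.50,
                        fixation_duration_mean_ms = 435.13),
      age_group_profile("adult", c(0.45, 0.45, 0.1), n_per_group,
                        trials_per_participant = n_scenes,
                        fixations_per_trial_mean = 15.96,
                        fixation_duration_mean_ms = 297.38,
                        center_start_fail_rate = 0,
                        outside_only_rate = 0)
    ),
    seed = seed
  )
}

#' Generate a complete synthetic study
#'
#' Simulates scenes, every participant's trials and fixations, every fMRI
#' subject's voxel patterns for every ROI, and per-scene salience maps
#' (the level-1 map doubles as the salience nuisance, which makes the
#' salience-partialed null exact for a pure-salience viewer). Optionally
#' writes the bundle to disk.
#'
#' @param config a [study_config()].
#' @param dir optional output directory; if given, writes `fixations.tsv`,
#'   `voxels.csv`, `salience/<scene>.txt`, `ground_truth.json` and
#'   `manifest.json` (file hashes), creating the directory if needed.
#' @return A list of class `"study_bundle"`: `config`, `scenes`,
#'   `fixations` (a `"fixation_report"`), `voxel_sets` (list of
#'   `"voxel_patterns"`), `salience` (named list of matrices), and, when
#'   written, `manifest`.
#' @export
generate_study <- function(config = study_config(), dir = NULL) {
  stopifnot(inherits(config, "study_config"))
  scenes <- make_scene_features(config$n_scenes, config$H, config$W,
                                config$L, config$smoothness,
                                config$contrast, config$embed_cells,
                                seed = derive_seed(config$seed, "scenes"))
  scene_ids <- vapply(scenes, `[[`, "", "scene_id")

  fix_rows <- list()
  pi <- 0L
  for (prof in config$profiles) {
    for (p in seq_len(prof$n_participants)) {
      pi <- pi + 1L
      pid <- sprintf("%s%03d", prof$name, p)
      pseed <- derive_seed(config$seed, paste0("participant:", pid))
      plan <- with_seed(pseed, {
        k <- prof$trials_per_participant
        sc <- if (k <= config$n_scenes) {
          sample(scene_ids, k)
        } else {
          sample(scene_ids, k, replace = TRUE)
        }
        # the Poisson draw is the *total* fixation count per trial; the
        # prepended center fixation is one of them
        list(scenes = sc,
             n_fix = pmax(0L, stats::rpois(
               k, prof$fixations_per_trial_mean) - 1L),
             center_fail = stats::runif(k) < prof$center_start_fail_rate,
             outside_only = stats::runif(k) < prof$outside_only_rate)
      })
      for (tr in seq_along(plan$scenes)) {
        sc <- scenes[[match(plan$scenes[tr], scene_ids)]]
        t <- simulate_fixations(
          sc, prof, plan$n_fix[tr],
          seed = derive_seed(pseed, paste0("trial:", tr)),
          participant_id = pid, trial_index = tr
        )
        if (plan$center_fail[tr]) t$started_at_center <- FALSE
        if (plan$outside_only[tr]) t$x_px <- t$x_px + config$W
        fix_rows[[length(fix_rows) + 1L]] <- t
      }
    }
  }
  fixations <- validate_fixations(do.call(rbind, fix_rows))

  voxel_sets <- list()
  for (s in seq_len(config$n_fmri_subjects)) {
    for (roi in config$rois) {
      vs <- simulate_voxel_patterns(
        scenes, roi, fmri_subject_seed = derive_seed(config$seed,
                                                     paste0("fmri:", s)))
      vs$fmri_subject_id <- sprintf("fmri%02d", s)
      voxel_sets[[paste(vs$fmri_subject_id, roi$roi_id, sep = "|")]] <- vs
    }
  }

  salience <- lapply(scenes, function(s) s$level_maps[[1L]])
  names(salience) <- scene_ids

  bundle <- structure(list(config = config, scenes = scenes,
                           fixations = fixations, voxel_sets = voxel_sets,
                           salience = salience),
                      class = "study_bundle")
  if (!is.null(dir)) bundle <- write_study_bundle(bundle, dir)
  bundle
}

ground_truth_manifest <- function(config) {
  list(
    n_scenes = config$n_scenes, H = config$H, W = config$W, L = config$L,
    smoothness = config$smoothness, contrast = config$contrast,
    embed_cells = config$embed_cells,
    n_fmri_subjects = config$n_fmri_subjects, seed = config$seed,
    profiles = lapply(config$profiles, function(p) {
      p[c("name", "mixture_weights", "n_participants",
          "trials_per_participant", "fixations_per_trial_mean",
          "fixation_duration_mean_ms", "total_look_ms_mean",
          "center_start_fail_rate", "outside_only_rate")]
    }),
    rois = lapply(config$rois, function(r) {
      r[c("roi_id", "level_loadings", "n_voxels", "noise_sd")]
    })
  )
}

#' Write / read a study bundle on disk
#'
#' The bundle layout is `fixations.tsv` (tab-separated fixation report),
#' `voxels.csv` (long-format voxel patterns), `salience/<scene>.txt`
#' (per-scene text matrices) and `ground_truth.json`; `manifest.json`
#' records MD5 hashes of every file for reproducibility checks.
#'
#' @param bundle a `"study_bundle"`.
#' @param dir directory to write to (created if missing).
#' @return The bundle with a `manifest` element added (invisibly for the
#'   writer).
#' @export
write_study_bundle <- function(bundle, dir) {
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE)
  if (!ok) stopf("cannot create output directory: %s", dir)
  write_fixation_report(bundle$fixations, file.path(dir, "fixations.tsv"))
  write_voxel_patterns(bundle$voxel_sets, file.path(dir, "voxels.csv"))
  sdir <- file.path(dir, "salience")
  dir.create(sdir, showWarnings = FALSE)
  for (id in names(bundle$salience)) {
    write_text_matrix(bundle$salience[[id]],
                      file.path(sdir, paste0(id, ".txt")))
  }
  jsonlite::write_json(ground_truth_manifest(bundle$config),
                       file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  files <- c("fixations.tsv", "voxels.csv", "ground_truth.json",
             file.path("salience", paste0(names(bundle$salience), ".txt")))
  manifest <- list(files = as.list(stats::setNames(
    file_md5(file.path(dir, files)), files)),
    seed = bundle$config$seed)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  bundle$manifest <- manifest
  bundle$dir <- dir
  invisible(bundle)
}

#' @rdname write_study_bundle
#' @export
read_study_bundle <- function(dir) {
  if (!dir.exists(dir)) stopf("no such bundle directory: %s", dir)
  fixations <- read_fixation_report(file.path(dir, "fixations.tsv"))
  voxel_sets <- read_voxel_patterns(file.path(dir, "voxels.csv"))
  sfiles <- list.files(file.path(dir, "salience"), pattern = "\\.txt$",
                       full.names = TRUE)
  salience <- lapply(sfiles, read_text_matrix)
  names(salience) <- sub("\\.txt$", "", basename(sfiles))
  gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                            simplifyVector = TRUE)
  structure(list(config = gt, fixations = fixations,
                 voxel_sets = voxel_sets, salience = salience, dir = dir),
            class = "study_bundle")
}

#' @export
print.study_bundle <- function(x, ...) {
  cat(sprintf(
    "Synthetic study bundle: %d fixations, %d participants, %d voxel sets\n",
    nrow(x$fixations), length(unique(x$fixations$participant_id)),
    length(x$voxel_sets)))
  invisible(x)
}
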