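# End-to-end orchestration: exclusions -> density maps -> RSMs ->
# similarity -> noise ceilings -> group inference, from an in-memory or
# on-disk study bundle, with a reproducibility manifest.

#' Run the full gaze-to-brain RSA pipeline
#'
#' Applies the trial- and subject-level exclusion rules, builds fixation
#' density maps and per-participant gaze RSMs, builds per-fMRI-subject ROI
#' RSMs, computes per-participant x ROI Spearman similarity (averaged over
#' fMRI subjects, each computed on the scenes that participant viewed),
#' optionally the salience-partialed variant and leave-one-out noise
#' ceilings, and fits the age-by-ROI mixed model (infants) plus a separate
#' ROI-only model for adults.
#'
#' @param bundle a `"study_bundle"` from [generate_study()] /
#'   [read_study_bundle()], or a directory path to one.
#' @param params a [density_map_params()]; if `NULL`, the image extent is
#'   taken from the bundle and the smoothing sd is 7.21 px for full-scale
#'   (1000 px) images or 2.5 px for reduced-scale (< 256 px) images.
#' @param roi_specs optional named list mapping composite ROI names to
#'   character vectors of component ROI ids to concatenate voxel-wise
#'   (e.g. `list(V1 = c("V1v", "V1d"))`); by default each ROI in the
#'   bundle is analyzed as-is.
#' @param partial_on_salience also compute salience-partialed similarity
#'   using the bundle's salience maps as the nuisance.
#' @param compute_noise_ceiling estimate gaze, fMRI and combined noise
#'   ceilings per age group x ROI.
#' @param fit_models fit the mixed models (can be disabled when only the
#'   similarity table is needed).
#' @param min_trials subject-level usable-trial criterion.
#' @param alpha significance level for post hoc flags.
#' @param method model-fitting route passed to [fit_mixed_model()].
#' @return An object of class `"rsa_study"` with elements
#'   `similarity` (tidy table: participant_id, age_group, roi_id, rho,
#'   rho_partial, n_items), `exclusions`, `subject_exclusions`,
#'   `looking_stats`, `noise_ceilings`, `models` (infant and adult fits,
#'   EMMs, post hoc and between-age contrasts), and `manifest`.
#' @export
run_study <- function(bundle, params = NULL, roi_specs = NULL,
                      partial_on_salience = TRUE,
                      compute_noise_ceiling = TRUE, fit_models = TRUE,
                      min_trials = 18L, alpha = 0.05,
                      method = c("lmm", "anova")) {
  method <- match.arg(method)
  if (is.character(bundle)) bundle <- read_study_bundle(bundle)
  stopifnot(inherits(bundle, "study_bundle"))
  H <- bundle$config$H %||% 1000L
  W <- bundle$config$W %||% 1000L
  if (is.null(params)) {
    params <- density_map_params(image_h = H, image_w = W,
                                 sigma_px = if (W < 256) 2.5 else 7.21)
  }

  # stage 1: exclusions
  excl <- apply_trial_exclusions(bundle$fixations, params)
  subj <- apply_subject_exclusion(excl$fixations, min_trials = min_trials)
  kept <- subj$fixations
  if (nrow(kept) == 0L) stopf("preprocess: no usable trials remain")
  looking <- compute_looking_stats(kept)

  # stage 2: density maps and gaze RSMs (per participant, viewed scenes)
  maps <- density_maps(kept, params)
  gaze_rsms <- list()
  for (pid in names(maps)) {
    pm <- maps[[pid]]
    if (length(pm) < 3L) next  # too few scenes for an RSM
    vecs <- do.call(rbind, lapply(pm, as.vector))
    rownames(vecs) <- names(pm)
    gaze_rsms[[pid]] <- build_rsm(vecs, source = "gaze", owner_id = pid)
  }
  if (length(gaze_rsms) == 0L) stopf("rsm: no participant viewed >= 3 scenes")

  # stage 3: fMRI RSMs per subject x ROI (with optional concatenation)
  voxel_sets <- resolve_roi_specs(bundle$voxel_sets, roi_specs)
  fmri_rsms <- lapply(voxel_sets, function(vs) {
    build_rsm(vs$patterns, source = "fmri",
              owner_id = paste(vs$fmri_subject_id, vs$roi_id, sep = "|"))
  })
  roi_ids <- sort(unique(vapply(voxel_sets, `[[`, "", "roi_id")))
  fmri_subjects <- sort(unique(vapply(voxel_sets, `[[`, "",
                                      "fmri_subject_id")))

  # salience RSMs per participant (restricted to viewed scenes)
  salience_rsm_for <- function(scenes) {
    vecs <- do.call(rbind, lapply(bundle$salience[scenes], as.vector))
    rownames(vecs) <- scenes
    build_rsm(vecs, source = "salience")
  }

  # stage 4: similarity estimates
  age_of <- tapply(as.character(kept$age_group), kept$participant_id,
                   function(a) a[1L])
  sim_rows <- list()
  for (pid in names(gaze_rsms)) {
    g_rsm <- gaze_rsms[[pid]]
    scenes <- rsm_items(g_rsm)
    sal_rsm <- if (partial_on_salience) salience_rsm_for(scenes) else NULL
    for (roi in roi_ids) {
      rhos <- numeric(0)
      rhos_p <- numeric(0)
      for (fs in fmri_subjects) {
        vs_key <- paste(fs, roi, sep = "|")
        f_rsm <- fmri_rsms[[vs_key]]
        if (is.null(f_rsm)) stopf("similarity: ROI '%s' missing for %s",
                                  roi, fs)
        shared <- intersect(scenes, rsm_items(f_rsm))
        if (length(shared) < 3L) {
          stopf("similarity: too few shared scenes for %s / %s", pid,
                vs_key)
        }
        g_r <- restrict_rsm(g_rsm, shared)
        f_r <- restrict_rsm(f_rsm, shared)
        rhos <- c(rhos, representational_similarity(g_r, f_r))
        if (partial_on_salience) {
          rhos_p <- c(rhos_p, partial_representational_similarity(
            g_r, f_r, restrict_rsm(sal_rsm, shared)))
        }
      }
      est <- average_over_fmri_subjects(rhos, pid, roi,
                                        n_items = length(scenes))
      est$age_group <- unname(age_of[pid])
      est$rho_partial <- if (partial_on_salience) mean(rhos_p) else NA_real_
      sim_rows[[paste(pid, roi)]] <- est
    }
  }
  similarity <- do.call(rbind, lapply(sim_rows, as.data.frame))
  rownames(similarity) <- NULL
  similarity <- similarity[, c("participant_id", "age_group", "roi_id",
                               "rho", "rho_partial", "n_items",
                               "n_fmri_subjects_averaged")]

  # stage 5: noise ceilings
  ceilings <- NULL
  if (compute_noise_ceiling) {
    ceilings <- list()
    groups <- unique(similarity$age_group)
    gaze_nc <- lapply(groups, function(g) {
      pids <- names(age_of)[age_of == g]
      pids <- intersect(pids, names(gaze_rsms))
      if (length(pids) < 2L) return(NULL)
      noise_ceiling(gaze_rsms[pids])
    })
    names(gaze_nc) <- groups
    fmri_nc <- lapply(roi_ids, function(roi) {
      noise_ceiling(fmri_rsms[paste(fmri_subjects, roi, sep = "|")])
    })
    names(fmri_nc) <- roi_ids
    for (g in groups) {
      if (is.null(gaze_nc[[g]])) next
      for (roi in roi_ids) {
        ceilings[[paste(g, roi)]] <- combined_noise_ceiling(
          gaze_nc[[g]], fmri_nc[[roi]], roi_id = roi, group = g)
      }
    }
    ceilings <- do.call(rbind, ceilings)
    rownames(ceilings) <- NULL
  }

  # stage 6: group inference (infants together, adults separately)
  models <- NULL
  if (fit_models) {
    models <- list()
    infant <- similarity[similarity$age_group %in% c("young", "old"), ]
    if (length(unique(infant$age_group)) == 2L) {
      fit <- fit_mixed_model(infant, method = method)
      models$infant <- list(
        fit = fit, emm = estimated_marginal_means(fit),
        posthoc = posthoc_roi_contrasts(fit, alpha = alpha),
        between_age = between_age_contrasts(fit)
      )
    }
    adult <- similarity[similarity$age_group == "adult", ]
    if (nrow(adult) > 0L && length(unique(adult$roi_id)) >= 2L) {
      fit_a <- fit_mixed_model(adult, method = method)
      models$adult <- list(
        fit = fit_a, emm = estimated_marginal_means(fit_a),
        posthoc = posthoc_roi_contrasts(fit_a, alpha = alpha)
      )
    }
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("gazersa")),
    seed = bundle$config$seed,
    params = unclass(params),
    alpha = alpha, method = method, min_trials = min_trials,
    partial_on_salience = partial_on_salience,
    n_trials_read = attr(excl$report, "n_trials"),
    n_trials_kept = attr(excl$report, "n_kept"),
    exclusion_summary = attr(excl$report, "summary"),
    n_participants_kept = sum(subj$report$kept),
    n_fmri_subjects = length(fmri_subjects),
    roi_ids = roi_ids,
    config_hash = object_md5(bundle$config)
  )

  structure(list(similarity = similarity, exclusions = excl$report,
                 subject_exclusions = subj$report,
                 looking_stats = looking, noise_ceilings = ceilings,
                 models = models, manifest = manifest),
            class = "rsa_study")
}

# Expand composite-ROI specs by concatenating component voxel sets per
# fMRI subject; default is the identity mapping over the ROIs present.
resolve_roi_specs <- function(voxel_sets, roi_specs) {
  if (is.null(roi_specs)) return(voxel_sets)
  subjects <- unique(vapply(voxel_sets, `[[`, "", "fmri_subject_id"))
  out <- list()
  for (name in names(roi_specs)) {
    comps <- roi_specs[[name]]
    for (fs in subjects) {
      keys <- paste(fs, comps, sep = "|")
      missing <- keys[!keys %in% names(voxel_sets)]
      if (length(missing) > 0L) {
        stopf("ROI component(s) not found in voxel data: %s",
              paste(missing, collapse = ", "))
      }
      cs <- concatenate_roi(voxel_sets[keys], roi_id = name)
      out[[paste(fs, name, sep = "|")]] <- cs
    }
  }
  out
}

#' @export
print.rsa_study <- function(x, ...) {
  cat("Gaze-to-brain RSA study results\n")
  cat(sprintf("  %d similarity estimates (%d participants x %d ROIs)\n",
              nrow(x$similarity),
              length(unique(x$similarity$participant_id)),
              length(unique(x$similarity$roi_id))))
  cat(sprintf("  trials kept: %d / %d; participants kept: %d\n",
              x$manifest$n_trials_kept, x$manifest$n_trials_read,
              x$manifest$n_participants_kept))
  if (!is.null(x$models$infant)) {
    cat("  infant model:\n")
    print(x$models$infant$fit)
  }
  if (!is.null(x$models$adult)) {
    cat("  adult model:\n")
    print(x$models$adult$fit)
  }
  invisible(x)
}

#' @export
summary.rsa_study <- function(object, ...) {
  agg <- stats::aggregate(rho ~ age_group + roi_id, data = object$similarity,
                          FUN = mean)
  cat("Mean representational similarity (Spearman rho) per cell:\n")
  print(agg)
  if (!is.null(object$noise_ceilings)) {
    cat("\nCombined noise ceilings:\n")
    print(object$noise_ceilings[, c("group", "roi_id", "lower", "upper")])
  }
  invisible(agg)
}

#' @export
coef.rsa_study <- function(object, ...) {
  rbind(
    if (!is.null(object$models$infant)) object$models$infant$emm,
    if (!is.null(object$models$adult)) object$models$adult$emm
  )
}

#' Bar plot of estimated similarity with CIs and noise ceilings
#'
#' One bar per age group x ROI showing the estimated marginal mean
#' Spearman rho with its 95% CI, and, when available, whiskers marking the
#' lower and upper combined noise-ceiling bounds.
#'
#' @param x an `"rsa_study"`.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.rsa_study <- function(x, ...) {
  emm <- coef.rsa_study(x)
  if (is.null(emm)) stopf("no fitted models to plot")
  groups <- unique(emm$age_group)
  rois <- unique(emm$roi_id)
  hm <- matrix(0, length(groups), length(rois),
               dimnames = list(groups, rois))
  for (i in seq_len(nrow(emm))) {
    hm[emm$age_group[i], emm$roi_id[i]] <- emm$emmean[i]
  }
  ylim <- range(0, emm$lower, emm$upper,
                if (!is.null(x$noise_ceilings)) x$noise_ceilings$upper)
  mid <- graphics::barplot(hm, beside = TRUE, ylim = ylim * 1.15,
                           legend.text = groups,
                           ylab = "Spearman rho",
                           xlab = "ROI", ...)
  for (i in seq_len(nrow(emm))) {
    gx <- mid[match(emm$age_group[i], groups), match(emm$roi_id[i], rois)]
    graphics::arrows(gx, emm$lower[i], gx, emm$upper[i], angle = 90,
                     code = 3, length = 0.03)
    if (!is.null(x$noise_ceilings)) {
      nc <- x$noise_ceilings
      row <- nc[nc$group == emm$age_group[i] & nc$roi_id == emm$roi_id[i], ]
      if (nrow(row) == 1L) {
        graphics::segments(gx - 0.3, row$lower, gx + 0.3, row$lower,
                           col = "grey40", lty = 2)
        graphics::segments(gx - 0.3, row$upper, gx + 0.3, row$upper,
                           col = "grey40")
      }
    }
  }
  graphics::abline(h = 0)
  invisible(mid)
}

#' Write a results bundle to disk
#'
#' Emits tidy CSV tables (similarity estimates, ANOVA tables, estimated
#' marginal means, post hoc contrasts, noise ceilings, exclusion and
#' looking-time reports), a plain-text report in conventional
#' F(df1, df2)/t/p notation, a JSON manifest, and similarity figures.
#'
#' @param result an `"rsa_study"` from [run_study()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
report_study <- function(result, dir) {
  stopifnot(inherits(result, "rsa_study"))
  if (nrow(result$similarity) == 0L) stopf("empty similarity table")
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE)
  if (!ok) stopf("cannot create output directory: %s", dir)
  files <- character(0)
  wr <- function(obj, name) {
    p <- file.path(dir, name)
    utils::write.csv(as.data.frame(obj), p, row.names = FALSE)
    files <<- c(files, p)
  }
  wr(result$similarity, "similarity.csv")
  wr(result$exclusions, "exclusions.csv")
  wr(result$subject_exclusions, "subject_exclusions.csv")
  wr(result$looking_stats, "looking_stats.csv")
  if (!is.null(result$noise_ceilings)) {
    wr(result$noise_ceilings, "noise_ceilings.csv")
  }
  emm_all <- coef.rsa_study(result)
  if (!is.null(emm_all)) wr(emm_all, "emmeans.csv")
  report_lines <- c("Gaze-to-brain RSA report", "")
  for (who in names(result$models)) {
    m <- result$models[[who]]
    wr(m$fit$anova_table, sprintf("anova_%s.csv", who))
    wr(m$posthoc, sprintf("posthoc_%s.csv", who))
    if (!is.null(m$between_age)) {
      wr(m$between_age, sprintf("between_age_%s.csv", who))
    }
    report_lines <- c(report_lines, sprintf("== %s model ==", who))
    for (i in seq_len(nrow(m$fit$anova_table))) {
      a <- m$fit$anova_table[i, ]
      report_lines <- c(report_lines, sprintf(
        "%s: F(%d, %.0f) = %.2f, p %s", a$effect, a$df1, a$df2, a$F,
        if (a$p < 0.001) "< 0.001" else sprintf("= %.3f", a$p)))
    }
    for (i in seq_len(nrow(m$posthoc))) {
      ph <- m$posthoc[i, ]
      report_lines <- c(report_lines, sprintf(
        "%s | %s: t(%.0f) = %.2f, p = %.3f, Holm p = %.3f%s",
        ph$age_group, ph$contrast, ph$df, ph$t, ph$p, ph$p_holm,
        if (ph$significant) " *" else ""))
    }
    report_lines <- c(report_lines, "")
  }
  writeLines(report_lines, file.path(dir, "report.txt"))
  files <- c(files, file.path(dir, "report.txt"))
  # figures: all groups together plus one per fitted model
  fig <- function(name, expr) {
    p <- file.path(dir, name)
    grDevices::png(p, width = 900, height = 600)
    on.exit(grDevices::dev.off())
    force(expr)
    files <<- c(files, p)
  }
  if (!is.null(emm_all)) {
    fig("similarity_all.png", plot.rsa_study(result))
    for (who in names(result$models)) {
      sub <- result
      sub$models <- result$models[who]
      fig(sprintf("similarity_%s.png", who), plot.rsa_study(sub))
    }
  }
  jsonlite::write_json(result$manifest, file.path(dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  files <- c(files, file.path(dir, "run_manifest.json"))
  invisible(files)
}
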