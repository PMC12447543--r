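# Constructed fixation fixtures with hand-enumerable exclusion outcomes.

fix_row <- function(participant, trial, scene, idx, x, y, dur, center = TRUE,
                    age = "young") {
  data.frame(participant_id = participant, age_group = age,
             trial_index = trial, scene_id = scene, index_in_trial = idx,
             x_px = x, y_px = y, duration_ms = dur,
             started_at_center = center, stringsAsFactors = FALSE)
}

# A clean trial: center start, n in-image fixations of `dur` ms each.
good_trial <- function(participant, trial, scene = paste0("sc", trial),
                       n = 3L, dur = 400, age = "young") {
  do.call(rbind, lapply(seq_len(n) - 1L, function(i) {
    fix_row(participant, trial, scene, i, 40 + 5 * i, 40 + 3 * i, dur,
            age = age)
  }))
}

# 20-trial fixture on a 100 x 100 image with hand-enumerated outcomes:
#   trials 1-3   rule 1 (no center start; trial 3 also has < 3 fixations,
#                but rule 1 wins by order)
#   trials 4-5   rule 2 (all fixations off-image)
#   trials 6-8   rule 3 (two in-image fixations)
#   trials 9-10  rule 4 (three fixations summing to 950 ms)
#   trials 11-20 kept
exclusion_fixture <- function() {
  t1 <- good_trial("pA", 1L)
  t1$started_at_center <- FALSE
  t2 <- good_trial("pA", 2L)
  t2$started_at_center <- FALSE
  t3 <- good_trial("pA", 3L, n = 2L)
  t3$started_at_center <- FALSE
  t4 <- good_trial("pA", 4L)
  t4$x_px <- t4$x_px + 200   # off a 100 x 100 image
  t5 <- good_trial("pA", 5L)
  t5$y_px <- -t5$y_px - 10
  t6 <- good_trial("pA", 6L, n = 2L)
  t7 <- good_trial("pA", 7L, n = 2L)
  t8 <- good_trial("pA", 8L, n = 1L)
  t9 <- good_trial("pA", 9L)
  t9$duration_ms <- c(400, 300, 250)
  t10 <- good_trial("pA", 10L)
  t10$duration_ms <- c(500, 250, 200)
  kept <- lapply(11:20, function(i) good_trial("pA", i))
  do.call(rbind, c(list(t1, t2, t3, t4, t5, t6, t7, t8, t9, t10), kept))
}

fixture_params <- function() density_map_params(image_h = 100L,
                                                image_w = 100L,
                                                sigma_px = 2)

# Two subjects on either side of the usable-trial criterion: pX has 17
# clean trials, pY has 18.
subject_rule_fixture <- function() {
  rbind(
    do.call(rbind, lapply(1:17, function(i) good_trial("pX", i))),
    do.call(rbind, lapply(1:18, function(i) good_trial("pY", i)))
  )
}

# Small synthetic study used by pipeline tests.
tiny_config <- function(seed = 1L, n_per_group = 4L, n_scenes = 20L,
                        n_fmri = 3L) {
  cfg <- demo_config(seed = seed, n_per_group = n_per_group,
                     n_scenes = n_scenes)
  cfg$n_fmri_subjects <- as.integer(n_fmri)
  cfg
}
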