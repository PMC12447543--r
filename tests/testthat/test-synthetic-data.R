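# Synthetic study generator: scenes, fixations, voxel patterns, bundles.

test_that("scene feature maps are normalized probability fields", {
  sc <- make_scene_features(2, H = 64, W = 64, L = 3,
                            smoothness = c(2, 8, 32),
                            contrast = c(2, 1, 0.8), seed = 1)
  expect_length(sc, 2L)
  for (s in sc) {
    expect_length(s$level_maps, 3L)
    for (m in s$level_maps) {
      expect_equal(dim(m), c(64L, 64L))
      expect_true(all(m >= 0))
      expect_lt(abs(sum(m) - 1), 1e-9)
    }
    for (e in s$level_embeddings) expect_length(e, 64L)
  }
  # embeddings are the block means of the corresponding map
  e1 <- gazersa:::block_mean_embedding(sc[[1]]$level_maps[[1]], 8L)
  expect_equal(sc[[1]]$level_embeddings[[1]], e1)
})

test_that("scene generation is deterministic and validates scales", {
  a <- make_scene_features(3, seed = 5)
  b <- make_scene_features(3, seed = 5)
  expect_identical(a, b)
  c <- make_scene_features(3, seed = 6)
  expect_false(identical(a[[1]]$level_maps[[1]], c[[1]]$level_maps[[1]]))
  expect_error(make_scene_features(3, smoothness = c(8, 8, 32)),
               "increase in abstraction scale")
  expect_error(make_scene_features(1), "at least 2 scenes")
})

test_that("fixations sample the planted mixture distribution", {
  sc <- make_scene_features(2, H = 32, W = 32, L = 3,
                            smoothness = c(2, 6, 12), embed_cells = 8,
                            seed = 3)[[1]]
  prof <- age_group_profile("young", c(1, 0, 0), 1L)
  t0 <- simulate_fixations(sc, prof, 0L, seed = 1)
  expect_equal(nrow(t0), 1L)
  expect_equal(t0$x_px, 15.5)   # centre of a 32-px image, 0-based
  expect_true(t0$started_at_center)

  t1 <- simulate_fixations(sc, prof, 5L, seed = 9)
  t2 <- simulate_fixations(sc, prof, 5L, seed = 9)
  expect_identical(t1, t2)

  # large-n histogram recovers the level-1 map better than the level-3 map
  big <- simulate_fixations(sc, prof, 100000L, seed = 11)
  h <- matrix(0, 32, 32)
  xi <- round(big$x_px[-1]) + 1L
  yi <- round(big$y_px[-1]) + 1L
  for (k in seq_along(xi)) h[yi[k], xi[k]] <- h[yi[k], xi[k]] + 1
  r1 <- cor(as.vector(h), as.vector(sc$level_maps[[1]]))
  r3 <- cor(as.vector(h), as.vector(sc$level_maps[[3]]))
  expect_gt(r1, 0.95)
  expect_gt(r1, r3)

  # degenerate mixture is rejected
  zero_scene <- sc
  zero_scene$level_maps[[1]] <- matrix(0, 32, 32)
  expect_error(simulate_fixations(zero_scene, prof, 3L, seed = 1),
               "all-zero map")
  expect_error(simulate_fixations(sc, age_group_profile("young", c(1, 0),
                                                        1L), 3L, 1),
               "weights but scene")
})

test_that("age group profiles validate mixture weights", {
  expect_error(age_group_profile("young", c(0.5, 0.4), 10L), "sum to 1")
  expect_error(age_group_profile("young", c(1.2, -0.2, 0), 10L), ">= 0")
  p <- age_group_profile("adult", c(0.45, 0.45, 0.1), 45L,
                         fixations_per_trial_mean = 15.96,
                         fixation_duration_mean_ms = 297.38)
  expect_equal(p$total_look_ms_mean, 15.96 * 297.38)
})

test_that("noise-free single-level voxel patterns preserve the embedding RSM", {
  sc <- make_scene_features(6, H = 32, W = 32, smoothness = c(2, 6, 12),
                            embed_cells = 4, seed = 2)
  roi <- roi_profile("r1", c(1, 0, 0), n_voxels = 40L, noise_sd = 0)
  vp <- simulate_voxel_patterns(sc, roi, fmri_subject_seed = 7L)
  emb <- do.call(rbind, lapply(sc, function(s) s$level_embeddings[[1]]))
  rownames(emb) <- vapply(sc, `[[`, "", "scene_id")
  rsm_pat <- build_rsm(vp$patterns, source = "fmri")
  rsm_emb <- build_rsm(emb, source = "fmri")
  expect_equal(unclass(rsm_pat), unclass(rsm_emb), tolerance = 1e-10)
})

test_that("different fMRI subjects share geometry but not voxels", {
  sc <- make_scene_features(8, H = 32, W = 32, smoothness = c(2, 6, 12),
                            embed_cells = 4, seed = 4)
  roi <- roi_profile("r1", c(0.7, 0.3, 0), n_voxels = 30L, noise_sd = 0.01)
  v1 <- simulate_voxel_patterns(sc, roi, fmri_subject_seed = 1L)
  v2 <- simulate_voxel_patterns(sc, roi, fmri_subject_seed = 2L)
  expect_false(isTRUE(all.equal(v1$patterns, v2$patterns)))
  r1 <- build_rsm(v1$patterns)
  r2 <- build_rsm(v2$patterns)
  expect_gt(cor(lower_triangle(r1), lower_triangle(r2)), 0)
})

test_that("voxel simulation validates its preconditions", {
  sc <- make_scene_features(4, H = 32, W = 32, smoothness = c(2, 6, 12),
                            embed_cells = 4, seed = 2)
  expect_error(simulate_voxel_patterns(sc[1], roi_profile("r", c(1, 0, 0)),
                                       1L), "at least 2 scenes")
  tight <- roi_profile("r", c(1, 0, 0), n_voxels = 10L)  # D = 16 > 10 - 1
  expect_error(simulate_voxel_patterns(sc, tight, 1L),
               "embedding dimension")
})

test_that("study bundles round-trip through disk and hash identically", {
  cfg <- tiny_config(seed = 17)
  dir1 <- file.path(tempdir(), "bundle1")
  dir2 <- file.path(tempdir(), "bundle2")
  b1 <- generate_study(cfg, dir = dir1)
  b2 <- generate_study(tiny_config(seed = 17), dir = dir2)
  expect_identical(b1$manifest$files, b2$manifest$files)

  back <- read_study_bundle(dir1)
  expect_equal(as.data.frame(back$fixations), as.data.frame(b1$fixations),
               tolerance = 1e-12)
  expect_setequal(names(back$voxel_sets), names(b1$voxel_sets))
  k <- names(b1$voxel_sets)[[1]]
  expect_equal(back$voxel_sets[[k]]$patterns, b1$voxel_sets[[k]]$patterns,
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(back$salience[["scene001"]], b1$salience[["scene001"]],
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(back$config$seed, cfg$seed)

  # a different seed changes the data
  b3 <- generate_study(tiny_config(seed = 18))
  expect_false(identical(b1$fixations$x_px, b3$fixations$x_px))
  expect_error(read_study_bundle(file.path(tempdir(), "nope")),
               "no such bundle")
})

test_that("configurations without participants are rejected", {
  expect_error(study_config(profiles = list(
    age_group_profile("young", c(1, 0, 0), 0L))),
    "at least one participant")
})
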