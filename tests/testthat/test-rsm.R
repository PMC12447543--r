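# RSM construction, restriction, similarity, and partial similarity.

test_that("build_rsm reproduces pairwise Pearson correlations", {
  m <- rbind(a = c(0, 1, 2), b = c(0, 1, 2), c = c(3, 2, 1))
  r <- build_rsm(m)
  expect_equal(unname(r["a", "b"]), 1)
  expect_equal(unname(r["a", "c"]), -1)

  m2 <- rbind(a = c(1, 2, 4), b = c(1, 3, 9), c = c(2, 2, 1))
  r2 <- build_rsm(m2)
  expect_equal(unname(r2["a", "b"]), pearson_hand(c(1, 2, 4), c(1, 3, 9)),
               tolerance = 1e-12)
  expect_equal(round(unname(r2["a", "b"]), 4), 0.9959)

  set.seed(42)
  mr <- matrix(rnorm(7 * 12), 7, 12)
  rr <- build_rsm(mr)
  expect_lt(max(abs(rr - t(rr))), 1e-12)
  expect_equal(unname(diag(rr)), rep(1, 7))
  expect_true(all(rr >= -1 & rr <= 1))
})

test_that("zero-variance vectors are rejected with the item named", {
  m <- rbind(a = c(1, 1, 1), b = c(0, 1, 2), c = c(3, 2, 1))
  expect_error(build_rsm(m), "degenerate pattern.*a")
  expect_error(build_rsm(m[, 1, drop = FALSE]), "length >= 2")
  expect_error(build_rsm(m[1:2, ]), "at least 3 items")
})

test_that("concatenate_roi appends voxel axes and validates alignment", {
  sc <- c("s1", "s2", "s3")
  v1 <- voxel_patterns(matrix(rnorm(30), 3, 10), sc, "V1v", "f1")
  v2 <- voxel_patterns(matrix(rnorm(45), 3, 15), sc, "V1d", "f1")
  cc <- concatenate_roi(list(v1, v2), roi_id = "V1")
  expect_equal(ncol(cc$patterns), 25L)
  expect_equal(cc$roi_id, "V1")
  expect_equal(cc$patterns[, 1:10], v1$patterns)

  v3 <- voxel_patterns(matrix(rnorm(30), 3, 10), rev(sc), "V1d", "f1")
  expect_error(concatenate_roi(list(v1, v3)), "scene mismatch")
  v4 <- voxel_patterns(matrix(rnorm(30), 3, 10), sc, "V1d", "f2")
  expect_error(concatenate_roi(list(v1, v4)), "subject mismatch")
  expect_identical(concatenate_roi(list(v1)), v1)
})

test_that("restrict_rsm extracts the named submatrix", {
  set.seed(1)
  m <- matrix(rnorm(5 * 9), 5, 9,
              dimnames = list(paste0("s", 1:5), NULL))
  r <- build_rsm(m)
  expect_equal(unclass(restrict_rsm(r, paste0("s", 1:5))), unclass(r))
  sub <- restrict_rsm(r, c("s4", "s1", "s3"))
  expect_equal(unname(unclass(sub)[1, 3]), unname(unclass(r)["s4", "s3"]))
  expect_equal(rownames(sub), c("s4", "s1", "s3"))
  expect_error(restrict_rsm(r, c("s1", "s2", "zz")), "unknown item")
  expect_error(restrict_rsm(r, c("s1", "s2")), "too few shared scenes")
})

test_that("restrict-then-build equals build-then-restrict", {
  set.seed(7)
  m <- matrix(rnorm(6 * 20), 6, 20,
              dimnames = list(paste0("s", 1:6), NULL))
  keep <- c("s2", "s5", "s6", "s1")
  a <- restrict_rsm(build_rsm(m), keep)
  b <- build_rsm(m[keep, ])
  expect_equal(unclass(a), unclass(b), tolerance = 1e-12)
})

test_that("representational similarity is Spearman rho over lower triangles", {
  set.seed(3)
  m <- matrix(rnorm(4 * 16), 4, 16, dimnames = list(paste0("s", 1:4), NULL))
  r <- build_rsm(m)
  expect_equal(representational_similarity(r, r), 1)

  tri_to_rsm <- function(v, ids) {
    n <- length(ids)
    x <- diag(n)
    x[lower.tri(x)] <- v
    x <- x + t(x) - diag(n)
    dimnames(x) <- list(ids, ids)
    gazersa:::new_rsm(x)
  }
  a <- tri_to_rsm(c(0.1, 0.2, 0.3), c("i", "j", "k"))
  b <- tri_to_rsm(c(0.6, 0.5, 0.4), c("i", "j", "k"))
  expect_equal(representational_similarity(a, b), -1)

  x <- tri_to_rsm(c(0.1, 0.4, 0.2, 0.5, 0.3, 0.6), paste0("s", 1:4))
  y <- tri_to_rsm(c(0.2, 0.3, 0.1, 0.6, 0.4, 0.5), paste0("s", 1:4))
  expect_equal(representational_similarity(x, y),
               spearman_oracle(lower_triangle(x), lower_triangle(y)),
               tolerance = 1e-12)

  cst <- tri_to_rsm(rep(0.5, 6), paste0("s", 1:4))
  expect_error(representational_similarity(cst, y), "degenerate RSM")
  m2 <- m
  rownames(m2) <- paste0("t", 1:4)
  expect_error(representational_similarity(r, build_rsm(m2)),
               "share item ids")
})

test_that("similarity is invariant to increasing transforms of a triangle", {
  tri_to_rsm <- function(v, ids) {
    n <- length(ids)
    x <- diag(n)
    x[lower.tri(x)] <- v
    x <- x + t(x) - diag(n)
    dimnames(x) <- list(ids, ids)
    gazersa:::new_rsm(x)
  }
  set.seed(11)
  for (i in 1:5) {
    v1 <- runif(10, -1, 1)
    v2 <- runif(10, -1, 1)
    ids <- paste0("s", 1:5)
    base <- representational_similarity(tri_to_rsm(v1, ids),
                                        tri_to_rsm(v2, ids))
    warped <- representational_similarity(
      tri_to_rsm(tanh(3 * v1) + 0.1, ids),   # strictly increasing
      tri_to_rsm(v2, ids))
    expect_equal(base, warped, tolerance = 1e-12)
  }
})

test_that("averaging over fMRI subjects is the arithmetic mean", {
  e <- average_over_fmri_subjects(c(0.1, 0.2, 0.3), "p1", "V1", 30L)
  expect_equal(e$rho, 0.2)
  expect_equal(e$n_fmri_subjects_averaged, 3L)
  expect_equal(average_over_fmri_subjects(0.42)$rho, 0.42)
  expect_equal(average_over_fmri_subjects(rep(0.13, 8))$rho, 0.13)
  expect_equal(average_over_fmri_subjects(rep(0.13, 8))$
                 n_fmri_subjects_averaged, 8L)
  expect_error(average_over_fmri_subjects(numeric(0)), "at least one")
})

test_that("partial similarity residualizes ranks on the nuisance", {
  set.seed(5)
  m <- matrix(rnorm(5 * 24), 5, 24, dimnames = list(paste0("s", 1:5), NULL))
  g <- build_rsm(m)
  f <- build_rsm(matrix(rnorm(5 * 24), 5, 24,
                        dimnames = list(paste0("s", 1:5), NULL)))
  # nuisance identical to gaze: residual of x on itself is zero
  expect_lt(abs(partial_representational_similarity(g, f, g)), 1e-10)

  # matches the textbook partial-correlation formula on rank correlations
  for (seed in 1:4) {
    set.seed(seed)
    ids <- paste0("s", 1:6)
    mk <- function() build_rsm(matrix(rnorm(6 * 30), 6, 30,
                                      dimnames = list(ids, NULL)))
    x <- mk(); y <- mk(); z <- mk()
    rxy <- spearman_oracle(lower_triangle(x), lower_triangle(y))
    rxz <- spearman_oracle(lower_triangle(x), lower_triangle(z))
    ryz <- spearman_oracle(lower_triangle(y), lower_triangle(z))
    expect_equal(partial_representational_similarity(x, y, z),
                 partial_formula(rxy, rxz, ryz), tolerance = 1e-10)
  }
})

test_that("an orthogonal nuisance leaves plain rho unchanged", {
  tri_to_rsm <- function(v, ids) {
    n <- length(ids)
    x <- diag(n)
    x[lower.tri(x)] <- v
    x <- x + t(x) - diag(n)
    dimnames(x) <- list(ids, ids)
    gazersa:::new_rsm(x)
  }
  # 6 items -> 15 lower-triangle entries; these rank permutations satisfy
  # cor(rank(z), rank(x)) == 0 == cor(rank(z), rank(y)) exactly
  ids <- paste0("s", 1:6)
  x <- (1:15) / 16
  y <- c(7, 4, 5, 3, 8, 9, 6, 1, 15, 11, 13, 12, 10, 14, 2) / 16
  z <- c(4, 13, 2, 14, 11, 12, 1, 5, 7, 6, 10, 15, 8, 3, 9) / 16
  expect_equal(cor(rank(z), rank(x)), 0)
  expect_equal(cor(rank(z), rank(y)), 0)
  plain <- representational_similarity(tri_to_rsm(x, ids),
                                       tri_to_rsm(y, ids))
  partial <- partial_representational_similarity(
    tri_to_rsm(x, ids), tri_to_rsm(y, ids), tri_to_rsm(z, ids))
  expect_equal(partial, plain, tolerance = 1e-10)
})

test_that("voxel pattern CSV round-trips", {
  sc <- paste0("s", 1:4)
  sets <- list(
    `f1|A` = voxel_patterns(matrix(rnorm(20), 4, 5), sc, "A", "f1"),
    `f1|B` = voxel_patterns(matrix(rnorm(12), 4, 3), sc, "B", "f1")
  )
  path <- tempfile(fileext = ".csv")
  write_voxel_patterns(sets, path)
  back <- read_voxel_patterns(path)
  expect_setequal(names(back), names(sets))
  expect_equal(back[["f1|A"]]$patterns, sets[["f1|A"]]$patterns,
               tolerance = 1e-12, ignore_attr = TRUE)
  # missing column is a schema error
  d <- utils::read.csv(path)
  utils::write.csv(d[, setdiff(names(d), "voxel_index")], path,
                   row.names = FALSE)
  expect_error(read_voxel_patterns(path), "missing column")
})
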