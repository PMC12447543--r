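# Representational similarity matrices and RSM-to-RSM similarity.
#
# An RSM is the item-by-item matrix of Pearson correlations between response
# vectors (gaze density maps flattened to vectors, or voxel activation
# patterns). Representational similarity between two RSMs is the Spearman
# rank correlation of their strictly-lower-triangle entries.

#' Build a representational similarity matrix
#'
#' Computes the item-by-item Pearson correlation matrix of a set of response
#' vectors (one vector per item). Used both for gaze density maps (each map
#' flattened to a pixel vector) and for voxel activation patterns (each
#' scene's pattern across voxels).
#'
#' @param vectors numeric matrix with one row per item (items x features),
#'   or a named list of equal-length numeric vectors.
#' @param item_ids character vector of item identifiers; defaults to the
#'   row names of `vectors`.
#' @param source label recorded on the result, e.g. `"gaze"` or `"fmri"`.
#' @param owner_id identifier of the participant or fMRI subject the RSM
#'   belongs to.
#' @return An object of class `"rsm"`: the correlation matrix with item ids
#'   as dimnames and attributes `source` and `owner_id`. The diagonal is 1
#'   and the matrix is exactly symmetric.
#' @examples
#' m <- rbind(a = c(1, 2, 4), b = c(1, 3, 9), c = c(3, 2, 1))
#' build_rsm(m)
#' @export
build_rsm <- function(vectors, item_ids = NULL, source = "gaze",
                      owner_id = NA_character_) {
  if (is.list(vectors) && !is.data.frame(vectors)) {
    lens <- lengths(vectors)
    if (length(unique(lens)) != 1L) stopf("all vectors must have equal length")
    vectors <- do.call(rbind, vectors)
  }
  if (!is.matrix(vectors)) stopf("vectors must be a matrix or list of vectors")
  if (is.null(item_ids)) item_ids <- rownames(vectors)
  if (is.null(item_ids)) item_ids <- as.character(seq_len(nrow(vectors)))
  if (nrow(vectors) < 3L) stopf("need at least 3 items to build an RSM")
  if (ncol(vectors) < 2L) stopf("response vectors must have length >= 2")
  v <- apply(vectors, 1L, stats::var)
  if (any(v == 0 | !is.finite(v))) {
    bad <- item_ids[which(v == 0 | !is.finite(v))]
    stopf("degenerate pattern (zero variance) for item(s): %s",
          paste(bad, collapse = ", "))
  }
  r <- stats::cor(t(vectors))
  r <- (r + t(r)) / 2
  diag(r) <- 1
  dimnames(r) <- list(item_ids, item_ids)
  new_rsm(r, source = source, owner_id = owner_id)
}

new_rsm <- function(values, source = "gaze", owner_id = NA_character_) {
  stopifnot(is.matrix(values), nrow(values) == ncol(values))
  if (max(abs(values - t(values))) > 1e-12) stopf("RSM must be symmetric")
  structure(values, class = c("rsm", "matrix"),
            source = source, owner_id = owner_id)
}

#' @export
print.rsm <- function(x, ...) {
  cat(sprintf("RSM (%s%s): %d items\n", attr(x, "source"),
              if (!is.na(attr(x, "owner_id")))
                paste0(", owner ", attr(x, "owner_id")) else "",
              nrow(x)))
  print(unclass(x)[seq_len(min(6L, nrow(x))), seq_len(min(6L, ncol(x)))])
  invisible(x)
}

rsm_items <- function(rsm) rownames(rsm)

#' Strictly-lower-triangle entries of an RSM
#'
#' @param rsm an `"rsm"` object (or plain square matrix).
#' @return numeric vector of the below-diagonal entries in column-major
#'   order. The diagonal (constant 1) is excluded, as is standard in RSA.
#' @export
lower_triangle <- function(rsm) {
  m <- unclass(rsm)
  m[lower.tri(m, diag = FALSE)]
}

#' Restrict an RSM to a subset of items
#'
#' Used to compare a participant's gaze RSM with an fMRI RSM over only the
#' scenes that participant actually viewed.
#'
#' @param rsm an `"rsm"` object.
#' @param scene_subset character vector of item ids (subset of the RSM's
#'   items), in the desired output order.
#' @return The row/column submatrix as an `"rsm"`.
#' @export
restrict_rsm <- function(rsm, scene_subset) {
  items <- rsm_items(rsm)
  unknown <- setdiff(scene_subset, items)
  if (length(unknown) > 0L) {
    stopf("unknown item(s) in subset: %s", paste(unknown, collapse = ", "))
  }
  if (length(scene_subset) < 3L) stopf("too few shared scenes (need >= 3)")
  new_rsm(unclass(rsm)[scene_subset, scene_subset, drop = FALSE],
          source = attr(rsm, "source"), owner_id = attr(rsm, "owner_id"))
}

#' Concatenate voxel pattern sets into a composite ROI
#'
#' Appends the voxel axes of several pattern sets (e.g. the ventral and
#' dorsal subdivisions V1v and V1d) into a single composite region before
#' RSM construction.
#'
#' @param pattern_sets list of `"voxel_patterns"` objects sharing the same
#'   fMRI subject and the same scenes in the same order.
#' @param roi_id identifier for the composite region.
#' @return A `"voxel_patterns"` object with the voxel columns concatenated
#'   in the order given.
#' @export
concatenate_roi <- function(pattern_sets, roi_id = NULL) {
  stopifnot(length(pattern_sets) >= 1L)
  ref <- pattern_sets[[1L]]
  for (ps in pattern_sets[-1L]) {
    if (!identical(ps$scene_ids, ref$scene_ids)) {
      stopf("scene mismatch across ROI components")
    }
    if (!identical(ps$fmri_subject_id, ref$fmri_subject_id)) {
      stopf("fMRI subject mismatch across ROI components")
    }
  }
  if (length(pattern_sets) == 1L && is.null(roi_id)) return(ref)
  voxel_patterns(
    patterns = do.call(cbind, lapply(pattern_sets, `[[`, "patterns")),
    scene_ids = ref$scene_ids,
    roi_id = roi_id %||% paste(vapply(pattern_sets, `[[`, "", "roi_id"),
                               collapse = "+"),
    fmri_subject_id = ref$fmri_subject_id
  )
}

#' Construct a voxel pattern set
#'
#' @param patterns numeric matrix, scenes x voxels.
#' @param scene_ids character vector naming the rows.
#' @param roi_id,fmri_subject_id identifiers.
#' @return An object of class `"voxel_patterns"`.
#' @export
voxel_patterns <- function(patterns, scene_ids, roi_id, fmri_subject_id) {
  stopifnot(is.matrix(patterns), nrow(patterns) == length(scene_ids))
  if (ncol(patterns) < 2L) stopf("need at least 2 voxels")
  rownames(patterns) <- scene_ids
  structure(list(patterns = patterns, scene_ids = as.character(scene_ids),
                 roi_id = roi_id, fmri_subject_id = fmri_subject_id),
            class = "voxel_patterns")
}

#' @export
print.voxel_patterns <- function(x, ...) {
  cat(sprintf("Voxel patterns: subject %s, ROI %s, %d scenes x %d voxels\n",
              x$fmri_subject_id, x$roi_id, nrow(x$patterns),
              ncol(x$patterns)))
  invisible(x)
}

check_aligned <- function(a, b) {
  if (!identical(rsm_items(a), rsm_items(b))) {
    stopf("RSMs must share item ids in the same order")
  }
}

#' Representational similarity between two RSMs
#'
#' The Spearman rank correlation between the strictly-lower-triangle entries
#' of a gaze RSM and an fMRI RSM over the same items. Ties receive average
#' ranks.
#'
#' @param gaze_rsm,fmri_rsm `"rsm"` objects over identical items in
#'   identical order.
#' @return Spearman rho (single number).
#' @export
representational_similarity <- function(gaze_rsm, fmri_rsm) {
  check_aligned(gaze_rsm, fmri_rsm)
  x <- lower_triangle(gaze_rsm)
  y <- lower_triangle(fmri_rsm)
  if (length(x) < 3L) stopf("need at least 3 items")
  if (stats::var(x) == 0 || stats::var(y) == 0) stopf("degenerate RSM")
  stats::cor(x, y, method = "spearman")
}

#' Partial representational similarity controlling for a nuisance RSM
#'
#' Rank-transforms the lower triangles of all three RSMs, residualizes the
#' gaze and fMRI ranks on the nuisance ranks by least squares (with
#' intercept), and returns the Pearson correlation of the residuals: a
#' partial Spearman correlation. Used to control for low-level physical
#' salience (e.g. a salience-model RSM) when relating gaze to cortex.
#'
#' @param gaze_rsm,fmri_rsm,nuisance_rsm `"rsm"` objects over identical
#'   items in identical order.
#' @return Partial Spearman rho.
#' @export
partial_representational_similarity <- function(gaze_rsm, fmri_rsm,
                                                nuisance_rsm) {
  check_aligned(gaze_rsm, fmri_rsm)
  check_aligned(gaze_rsm, nuisance_rsm)
  x <- rank(lower_triangle(gaze_rsm))
  y <- rank(lower_triangle(fmri_rsm))
  z <- rank(lower_triangle(nuisance_rsm))
  if (stats::var(z) == 0) stopf("degenerate nuisance RSM")
  if (stats::var(x) == 0 || stats::var(y) == 0) stopf("degenerate RSM")
  rx <- stats::lm.fit(cbind(1, z), x)$residuals
  ry <- stats::lm.fit(cbind(1, z), y)$residuals
  # a triangle collinear with the nuisance leaves only float-noise
  # residuals; its partial correlation is 0 by definition
  if (stats::var(rx) <= 1e-20 * stats::var(x) ||
      stats::var(ry) <= 1e-20 * stats::var(y)) {
    return(0)
  }
  stats::cor(rx, ry)
}

#' Average per-fMRI-subject similarity estimates
#'
#' Arithmetic mean of the Spearman rho values obtained against each fMRI
#' subject's RSM, yielding one similarity estimate per participant x ROI.
#' No Fisher-z transform is applied.
#'
#' @param per_subject_rhos numeric vector, one rho per fMRI subject.
#' @param participant_id,roi_id identifiers recorded on the estimate.
#' @param n_items number of shared scenes the rho values were computed on.
#' @param partialed_on optional nuisance identifier if the rhos are partial
#'   correlations.
#' @return A one-row data frame of class `"similarity_estimate"` with
#'   columns `participant_id`, `roi_id`, `rho`, `n_items`,
#'   `n_fmri_subjects_averaged`, `partialed_on`.
#' @export
average_over_fmri_subjects <- function(per_subject_rhos,
                                       participant_id = NA_character_,
                                       roi_id = NA_character_,
                                       n_items = NA_integer_,
                                       partialed_on = NA_character_) {
  if (length(per_subject_rhos) < 1L) stopf("need at least one rho value")
  if (any(!is.finite(per_subject_rhos))) stopf("non-finite rho value")
  out <- data.frame(
    participant_id = participant_id, roi_id = roi_id,
    rho = mean(per_subject_rhos), n_items = n_items,
    n_fmri_subjects_averaged = length(per_subject_rhos),
    partialed_on = partialed_on, stringsAsFactors = FALSE
  )
  class(out) <- c("similarity_estimate", "data.frame")
  out
}

#' Read / write voxel pattern sets (long-format CSV)
#'
#' The on-disk voxel container is a long-format CSV with columns
#' `fmri_subject`, `roi_id`, `scene_id`, `voxel_index`, `value`.
#'
#' @param path file path.
#' @return `read_voxel_patterns` returns a list of `"voxel_patterns"`
#'   objects, one per fMRI subject x ROI.
#' @export
read_voxel_patterns <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("fmri_subject", "roi_id", "scene_id", "voxel_index", "value")
  miss <- setdiff(need, names(d))
  if (length(miss) > 0L) {
    stopf("voxel file missing column(s): %s", paste(miss, collapse = ", "))
  }
  key <- interaction(d$fmri_subject, d$roi_id, drop = TRUE, sep = "|")
  lapply(split(d, key), function(g) {
    scenes <- unique(g$scene_id)
    vox <- sort(unique(g$voxel_index))
    m <- matrix(NA_real_, length(scenes), length(vox),
                dimnames = list(scenes, NULL))
    m[cbind(match(g$scene_id, scenes), match(g$voxel_index, vox))] <- g$value
    if (anyNA(m)) stopf("incomplete voxel grid for subject %s ROI %s",
                        g$fmri_subject[1L], g$roi_id[1L])
    voxel_patterns(m, scenes, g$roi_id[1L], g$fmri_subject[1L])
  })
}

#' @rdname read_voxel_patterns
#' @param pattern_sets list of `"voxel_patterns"` objects to serialize.
#' @export
write_voxel_patterns <- function(pattern_sets, path) {
  rows <- lapply(pattern_sets, function(ps) {
    data.frame(
      fmri_subject = ps$fmri_subject_id, roi_id = ps$roi_id,
      scene_id = rep(ps$scene_ids, times = ncol(ps$patterns)),
      voxel_index = rep(seq_len(ncol(ps$patterns)),
                        each = nrow(ps$patterns)),
      value = as.vector(ps$patterns), stringsAsFactors = FALSE
    )
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Export an RSM as a CSV matrix
#'
#' @param rsm an `"rsm"` object.
#' @param path file path; item ids become the header row and first column.
#' @export
write_rsm <- function(rsm, path) {
  utils::write.csv(as.data.frame(unclass(rsm)), path, row.names = TRUE)
  invisible(path)
}
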