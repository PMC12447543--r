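# Noise ceiling estimation for representational similarity.
#
# The ceiling brackets the highest RSM-to-RSM Spearman correlation one could
# expect given measurement noise, using the leave-one-out construction: the
# upper bound correlates each subject's RSM with the group mean RSM
# including that subject (optimistic); the lower bound correlates it with
# the mean of the *other* subjects' RSMs (conservative). Gaze and fMRI
# ceilings are estimated separately and combined by multiplication.

#' Leave-one-out noise ceiling over a set of RSMs
#'
#' @param rsms_by_subject list of `"rsm"` objects, one per subject. Items
#'   need not be identical across subjects: the mean RSM is the entrywise
#'   mean over the subjects that contribute each item pair, and each
#'   subject's rho is computed over that subject's own item pairs. With a
#'   shared item set this reduces to the standard construction.
#' @return A list of class `"noise_ceiling_bounds"` with elements `lower`
#'   and `upper` (and `n_subjects`).
#' @export
noise_ceiling <- function(rsms_by_subject) {
  n <- length(rsms_by_subject)
  if (n < 2L) stopf("need at least 2 subjects' RSMs")
  items <- sort(unique(unlist(lapply(rsms_by_subject, rsm_items))))
  k <- length(items)
  # stack RSMs on the union item set, NA where a subject lacks an item pair
  arr <- array(NA_real_, c(k, k, n), dimnames = list(items, items, NULL))
  for (i in seq_len(n)) {
    it <- rsm_items(rsms_by_subject[[i]])
    arr[it, it, i] <- unclass(rsms_by_subject[[i]])
  }
  tot <- apply(arr, c(1L, 2L), function(v) sum(v, na.rm = TRUE))
  cnt <- apply(arr, c(1L, 2L), function(v) sum(!is.na(v)))
  lt <- lower.tri(tot, diag = FALSE)
  rho_vs <- function(i, exclude_self) {
    mi <- arr[, , i]
    t2 <- tot
    c2 <- cnt
    if (exclude_self) {
      t2[!is.na(mi)] <- t2[!is.na(mi)] - mi[!is.na(mi)]
      c2[!is.na(mi)] <- c2[!is.na(mi)] - 1L
    }
    ok <- lt & !is.na(mi) & c2 > 0L
    x <- mi[ok]
    y <- (t2 / pmax(c2, 1L))[ok]
    if (length(x) < 3L || stats::var(x) == 0 || stats::var(y) == 0) {
      return(NA_real_)
    }
    stats::cor(x, y, method = "spearman")
  }
  upper <- mean(vapply(seq_len(n), rho_vs, 0, exclude_self = FALSE),
                na.rm = TRUE)
  lower <- mean(vapply(seq_len(n), rho_vs, 0, exclude_self = TRUE),
                na.rm = TRUE)
  structure(list(lower = lower, upper = upper, n_subjects = n),
            class = "noise_ceiling_bounds")
}

#' @export
print.noise_ceiling_bounds <- function(x, ...) {
  cat(sprintf("Noise ceiling bounds: [%.3f, %.3f] (%d subjects)\n",
              x$lower, x$upper, x$n_subjects))
  invisible(x)
}

#' Combine gaze and fMRI noise ceilings
#'
#' The attainable ceiling for gaze-to-brain similarity is limited by the
#' noise in both data sources, so the combined bounds are the products of
#' the source bounds: combined lower = gaze lower x fMRI lower, combined
#' upper = gaze upper x fMRI upper.
#'
#' @param gaze,fmri `"noise_ceiling_bounds"` objects (or lists with `lower`
#'   and `upper` in `[-1, 1]`).
#' @param roi_id,group identifiers recorded on the result.
#' @return A one-row data frame of class `"noise_ceiling"` with columns
#'   `roi_id`, `group`, `lower`, `upper`, `gaze_lower`, `gaze_upper`,
#'   `fmri_lower`, `fmri_upper`.
#' @export
combined_noise_ceiling <- function(gaze, fmri, roi_id = NA_character_,
                                   group = NA_character_) {
  for (b in list(gaze, fmri)) {
    if (any(abs(c(b$lower, b$upper)) > 1 + 1e-12)) {
      stopf("ceiling bounds must lie in [-1, 1]")
    }
  }
  out <- data.frame(
    roi_id = roi_id, group = group,
    lower = gaze$lower * fmri$lower, upper = gaze$upper * fmri$upper,
    gaze_lower = gaze$lower, gaze_upper = gaze$upper,
    fmri_lower = fmri$lower, fmri_upper = fmri$upper,
    stringsAsFactors = FALSE
  )
  class(out) <- c("noise_ceiling", "data.frame")
  out
}
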