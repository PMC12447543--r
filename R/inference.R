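# Group inference on per-participant similarity estimates.
#
# The model is a Gaussian linear mixed model with a random participant
# intercept:  rho ~ age * ROI + (1 | participant),
# fitted by REML with sum-to-zero contrasts and Type-III F tests. On a
# balanced complete design this is exactly the classical two-way
# mixed-design ANOVA decomposition (between factor: age; within factor:
# ROI), and a closed-form `method = "anova"` route exploiting that
# equivalence is provided for Monte-Carlo work. Adults are analyzed in a
# separate model with no age factor.

#' Fit the age-by-ROI mixed model
#'
#' @param table data frame with columns `participant_id`, `age_group`,
#'   `roi_id`, `rho`: one row per participant x ROI. With a single age
#'   group (e.g. adults) the age factor is omitted from the model.
#' @param method `"lmm"` fits via [lmerTest::lmer()] with Satterthwaite
#'   Type-III F tests; `"anova"` computes the classical balanced
#'   mixed-design ANOVA decomposition in closed form and requires a
#'   balanced complete design (identical ROI sets for every participant,
#'   equal group sizes). The two routes agree on balanced data.
#' @return An object of class `"rsa_mixed_model"` with elements
#'   `anova_table` (effect, F, df1, df2, p), `cell_means`, `varcomp`
#'   (subject-intercept and residual variances), `method`, and the mean
#'   squares used by the post hoc machinery.
#' @seealso [estimated_marginal_means()], [posthoc_roi_contrasts()],
#'   [between_age_contrasts()]
#' @export
fit_mixed_model <- function(table, method = c("lmm", "anova")) {
  method <- match.arg(method)
  d <- as.data.frame(table)
  need <- c("participant_id", "age_group", "roi_id", "rho")
  miss <- setdiff(need, names(d))
  if (length(miss) > 0L) {
    stopf("similarity table missing column(s): %s",
          paste(miss, collapse = ", "))
  }
  if (any(!is.finite(d$rho))) stopf("non-finite rho values")
  d$age_group <- factor(d$age_group, levels = age_level_order(d$age_group))
  d$roi_id <- factor(d$roi_id)
  d$participant_id <- factor(d$participant_id)
  if (nlevels(d$roi_id) < 2L) stopf("need at least 2 ROI levels")
  grp_n <- tapply(d$participant_id, d$age_group,
                  function(p) length(unique(p)))
  if (any(grp_n < 2L)) stopf("need at least 2 participants per age group")
  if (method == "anova") fit_balanced_anova(d) else fit_lmm(d)
}

# young < old < adult when those labels are used; otherwise order of
# appearance. Between-age contrasts are reported as later - earlier level
# (old - young).
age_level_order <- function(x) {
  u <- unique(as.character(x))
  known <- c("young", "old", "adult")
  c(known[known %in% u], setdiff(u, known))
}

cell_mean_table <- function(d) {
  agg <- stats::aggregate(rho ~ age_group + roi_id, data = d, FUN = mean)
  n <- stats::aggregate(rho ~ age_group + roi_id, data = d, FUN = length)
  data.frame(age_group = as.character(agg$age_group),
             roi_id = as.character(agg$roi_id), mean = agg$rho,
             n = n$rho, stringsAsFactors = FALSE)
}

fit_lmm <- function(d) {
  two_way <- nlevels(d$age_group) >= 2L
  form <- if (two_way) {
    rho ~ age_group * roi_id + (1 | participant_id)
  } else {
    rho ~ roi_id + (1 | participant_id)
  }
  ctr <- if (two_way) {
    list(age_group = stats::contr.sum, roi_id = stats::contr.sum)
  } else {
    list(roi_id = stats::contr.sum)
  }
  m <- suppressMessages(
    lmerTest::lmer(form, data = d, REML = TRUE, contrasts = ctr))
  if (lme4::isSingular(m, tol = 0)) {
    # zero subject variance is allowed; a failed fit is not
    if (!is.null(m@optinfo$conv$lme4$messages) &&
        any(grepl("failed", m@optinfo$conv$lme4$messages))) {
      stopf("mixed model failed to converge")
    }
  }
  a <- stats::anova(m, type = 3)
  anova_table <- data.frame(
    effect = gsub("age_group", "age", gsub("roi_id", "roi", rownames(a))),
    F = a$`F value`, df1 = a$NumDF, df2 = a$DenDF, p = a$`Pr(>F)`,
    stringsAsFactors = FALSE
  )
  rownames(anova_table) <- NULL
  vc <- as.data.frame(lme4::VarCorr(m))
  varcomp <- c(subject_intercept = vc$vcov[vc$grp == "participant_id"],
               residual = vc$vcov[vc$grp == "Residual"])
  structure(list(anova_table = anova_table, cell_means = cell_mean_table(d),
                 varcomp = varcomp, method = "lmm", model = m, data = d,
                 two_way = two_way),
            class = "rsa_mixed_model")
}

# Classical balanced mixed-design (split-plot) ANOVA in closed form.
fit_balanced_anova <- function(d) {
  tab <- table(d$participant_id, d$roi_id)
  if (any(tab != 1L)) {
    stopf("method 'anova' requires one row per participant x ROI")
  }
  subj <- levels(d$participant_id)
  rois <- levels(d$roi_id)
  r <- length(rois)
  Y <- matrix(NA_real_, length(subj), r, dimnames = list(subj, rois))
  Y[cbind(match(d$participant_id, subj), match(d$roi_id, rois))] <- d$rho
  grp <- d$age_group[match(subj, d$participant_id)]
  two_way <- nlevels(droplevels(grp)) >= 2L
  grp <- droplevels(grp)
  n_g <- table(grp)
  if (two_way && length(unique(n_g)) != 1L) {
    stopf("method 'anova' requires equal group sizes; use method = 'lmm'")
  }
  N <- nrow(Y)
  g <- nlevels(grp)
  grand <- mean(Y)
  m_s <- rowMeans(Y)
  m_j <- colMeans(Y)
  if (two_way) {
    m_gj <- apply(Y, 2L, function(col) tapply(col, grp, mean))  # g x r
    m_g <- rowMeans(m_gj)
    n <- as.integer(n_g[1L])
    ss_age <- r * n * sum((m_g - grand)^2)
    ss_subj <- r * sum((m_s - m_g[as.integer(grp)])^2)
    ss_roi <- N * sum((m_j - grand)^2)
    int_dev <- sweep(sweep(m_gj, 1L, m_g), 2L, m_j) + grand
    ss_int <- n * sum(int_dev^2)
    # residual: y - subject mean - cell mean + group mean
    fit_cell <- m_gj[cbind(rep(as.integer(grp), r),
                           rep(seq_len(r), each = N))]
    resid <- as.vector(Y) - m_s[rep(seq_len(N), r)] - fit_cell +
      m_g[rep(as.integer(grp), r)]
    ss_err <- sum(resid^2)
    df_age <- g - 1L
    df_subj <- N - g
    df_roi <- r - 1L
    df_int <- (g - 1L) * (r - 1L)
    df_err <- (N - g) * (r - 1L)
    ms_age <- ss_age / df_age
    ms_subj <- ss_subj / df_subj
    ms_roi <- ss_roi / df_roi
    ms_int <- ss_int / df_int
    ms_err <- ss_err / df_err
    anova_table <- data.frame(
      effect = c("age", "roi", "age:roi"),
      F = c(ms_age / ms_subj, ms_roi / ms_err, ms_int / ms_err),
      df1 = c(df_age, df_roi, df_int),
      df2 = c(df_subj, df_err, df_err),
      stringsAsFactors = FALSE
    )
  } else {
    n <- N
    ss_subj <- r * sum((m_s - grand)^2)
    ss_roi <- N * sum((m_j - grand)^2)
    resid <- as.vector(Y) - m_s[rep(seq_len(N), r)] -
      m_j[rep(seq_len(r), each = N)] + grand
    ss_err <- sum(resid^2)
    df_subj <- N - 1L
    df_roi <- r - 1L
    df_err <- (N - 1L) * (r - 1L)
    ms_subj <- ss_subj / df_subj
    ms_err <- ss_err / df_err
    anova_table <- data.frame(
      effect = "roi", F = (ss_roi / df_roi) / ms_err,
      df1 = df_roi, df2 = df_err, stringsAsFactors = FALSE
    )
  }
  anova_table$p <- stats::pf(anova_table$F, anova_table$df1,
                             anova_table$df2, lower.tail = FALSE)
  varcomp <- c(subject_intercept = max(0, (ms_subj - ms_err) / r),
               residual = ms_err)
  structure(list(anova_table = anova_table, cell_means = cell_mean_table(d),
                 varcomp = varcomp, method = "anova", model = NULL,
                 data = d, two_way = two_way,
                 ms = list(ms_subj = ms_subj, df_subj = df_subj,
                           ms_err = ms_err, df_err = df_err, r = r,
                           n_g = as.integer(n_g), groups = levels(grp))),
            class = "rsa_mixed_model")
}

#' @export
print.rsa_mixed_model <- function(x, ...) {
  cat(sprintf("Mixed model on similarity estimates (%s)\n",
              if (x$two_way) "rho ~ age * ROI + (1 | participant)"
              else "rho ~ ROI + (1 | participant)"))
  for (i in seq_len(nrow(x$anova_table))) {
    a <- x$anova_table[i, ]
    cat(sprintf("  %-8s F(%d, %.0f) = %.2f, p %s\n", a$effect, a$df1,
                a$df2, a$F,
                if (a$p < 0.001) "< 0.001" else sprintf("= %.3f", a$p)))
  }
  invisible(x)
}

satterthwaite_df <- function(a, ms1, df1, b, ms2, df2) {
  (a * ms1 + b * ms2)^2 / ((a * ms1)^2 / df1 + (b * ms2)^2 / df2)
}

#' Estimated marginal means per age group x ROI cell
#'
#' Model-based cell means with standard errors, degrees of freedom and 95%
#' confidence intervals, plus a flag for whether each interval excludes
#' zero (the chance level for representational similarity).
#'
#' @param fit an `"rsa_mixed_model"`.
#' @param level confidence level (default 0.95).
#' @return Data frame of class `"emm_result"` with columns `age_group`,
#'   `roi_id`, `emmean`, `se`, `df`, `lower`, `upper`, `excludes_zero`.
#' @export
estimated_marginal_means <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "rsa_mixed_model"))
  if (fit$method == "lmm") {
    spec <- if (fit$two_way) ~ age_group * roi_id else ~ roi_id
    s <- summary(emmeans::emmeans(fit$model, spec), level = level)
    out <- data.frame(
      age_group = if (fit$two_way) as.character(s$age_group)
                  else as.character(fit$data$age_group[1L]),
      roi_id = as.character(s$roi_id), emmean = s$emmean, se = s$SE,
      df = s$df, lower = s$lower.CL, upper = s$upper.CL,
      stringsAsFactors = FALSE
    )
  } else {
    ms <- fit$ms
    cm <- fit$cell_means
    n_g <- ms$n_g[match(cm$age_group,
                        ms$groups %||% unique(cm$age_group))]
    a <- 1 / (ms$r * n_g)
    b <- (ms$r - 1) / (ms$r * n_g)
    se <- sqrt(a * ms$ms_subj + b * ms$ms_err)
    df <- satterthwaite_df(a, ms$ms_subj, ms$df_subj, b, ms$ms_err,
                           ms$df_err)
    tcrit <- stats::qt(1 - (1 - level) / 2, df)
    out <- data.frame(
      age_group = cm$age_group, roi_id = cm$roi_id, emmean = cm$mean,
      se = se, df = df, lower = cm$mean - tcrit * se,
      upper = cm$mean + tcrit * se, stringsAsFactors = FALSE
    )
  }
  out$excludes_zero <- out$lower > 0 | out$upper < 0
  class(out) <- c("emm_result", "data.frame")
  out
}

#' Holm-Bonferroni step-down adjustment
#'
#' Step-down Holm adjustment of a family of p-values with monotonicity
#' enforcement, as applied to the within-age-group ROI contrasts.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same order as the input.
#' @export
holm_adjust <- function(p_values) {
  if (length(p_values) == 0L) return(numeric(0))
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1)) {
    stopf("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "holm")
}

#' Post hoc ROI contrasts within each age group
#'
#' Pairwise t contrasts between ROIs on the estimated marginal means,
#' computed within each age group, with Holm correction applied across the
#' ROI contrasts *within* each group (the correction family).
#'
#' @param fit an `"rsa_mixed_model"`.
#' @param alpha family-wise significance level (default 0.05).
#' @return Data frame of class `"posthoc_result"`: `age_group`, `contrast`,
#'   `estimate`, `se`, `df`, `t`, `p`, `p_holm`, `significant`.
#' @export
posthoc_roi_contrasts <- function(fit, alpha = 0.05) {
  stopifnot(inherits(fit, "rsa_mixed_model"))
  if (fit$method == "lmm") {
    spec <- if (fit$two_way) ~ roi_id | age_group else ~ roi_id
    prs <- summary(emmeans::contrast(emmeans::emmeans(fit$model, spec),
                                     "pairwise", adjust = "none"))
    out <- data.frame(
      age_group = if (fit$two_way) as.character(prs$age_group)
                  else as.character(fit$data$age_group[1L]),
      contrast = as.character(prs$contrast), estimate = prs$estimate,
      se = prs$SE, df = prs$df, t = prs$t.ratio, p = prs$p.value,
      stringsAsFactors = FALSE
    )
  } else {
    ms <- fit$ms
    cm <- fit$cell_means
    rois <- sort(unique(cm$roi_id))
    rows <- list()
    for (grp in unique(cm$age_group)) {
      n_g <- ms$n_g[match(grp, ms$groups %||% grp)]
      se <- sqrt(2 * ms$ms_err / n_g)
      for (i in seq_along(rois)) {
        for (j in seq_along(rois)) {
          if (i >= j) next
          mi <- cm$mean[cm$age_group == grp & cm$roi_id == rois[i]]
          mj <- cm$mean[cm$age_group == grp & cm$roi_id == rois[j]]
          tt <- (mi - mj) / se
          rows[[length(rows) + 1L]] <- data.frame(
            age_group = grp,
            contrast = paste(rois[i], "-", rois[j]),
            estimate = mi - mj, se = se, df = ms$df_err, t = tt,
            p = 2 * stats::pt(-abs(tt), ms$df_err),
            stringsAsFactors = FALSE
          )
        }
      }
    }
    out <- do.call(rbind, rows)
  }
  out$p_holm <- NA_real_
  for (grp in unique(out$age_group)) {
    sel <- out$age_group == grp
    out$p_holm[sel] <- holm_adjust(out$p[sel])
  }
  out$significant <- out$p_holm < alpha
  rownames(out) <- NULL
  class(out) <- c("posthoc_result", "data.frame")
  out
}

#' Between-age-group contrasts within each ROI
#'
#' t contrast for the difference between the two age groups (later level
#' minus earlier, i.e. old - young) separately for each ROI.
#'
#' @param fit an `"rsa_mixed_model"` fitted on two age groups.
#' @param roi_id optional single ROI to restrict to.
#' @return Data frame of class `"posthoc_result"`: `roi_id`, `contrast`,
#'   `estimate`, `se`, `df`, `t`, `p`.
#' @export
between_age_contrasts <- function(fit, roi_id = NULL) {
  stopifnot(inherits(fit, "rsa_mixed_model"))
  if (!fit$two_way) stopf("model has a single age group")
  if (fit$method == "lmm") {
    prs <- summary(emmeans::contrast(
      emmeans::emmeans(fit$model, ~ age_group | roi_id),
      "revpairwise", adjust = "none"))
    out <- data.frame(
      roi_id = as.character(prs$roi_id),
      contrast = as.character(prs$contrast), estimate = prs$estimate,
      se = prs$SE, df = prs$df, t = prs$t.ratio, p = prs$p.value,
      stringsAsFactors = FALSE
    )
  } else {
    ms <- fit$ms
    cm <- fit$cell_means
    groups <- ms$groups
    if (length(groups) != 2L) stopf("between-age contrasts need 2 groups")
    rows <- list()
    a <- sum(1 / ms$n_g) / ms$r
    b <- sum(1 / ms$n_g) * (ms$r - 1) / ms$r
    se <- sqrt(a * ms$ms_subj + b * ms$ms_err)
    df <- satterthwaite_df(a, ms$ms_subj, ms$df_subj, b, ms$ms_err,
                           ms$df_err)
    for (roi in sort(unique(cm$roi_id))) {
      m1 <- cm$mean[cm$age_group == groups[1L] & cm$roi_id == roi]
      m2 <- cm$mean[cm$age_group == groups[2L] & cm$roi_id == roi]
      tt <- (m2 - m1) / se
      rows[[length(rows) + 1L]] <- data.frame(
        roi_id = roi, contrast = paste(groups[2L], "-", groups[1L]),
        estimate = m2 - m1, se = se, df = df, t = tt,
        p = 2 * stats::pt(-abs(tt), df), stringsAsFactors = FALSE
      )
    }
    out <- do.call(rbind, rows)
  }
  if (!is.null(roi_id)) out <- out[out$roi_id %in% roi_id, ]
  rownames(out) <- NULL
  class(out) <- c("posthoc_result", "data.frame")
  out
}
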