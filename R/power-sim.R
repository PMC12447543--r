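# Monte-Carlo power and family-wise error simulations for the repeated
# measures design (between factor: age group; within factor: ROI; random
# participant intercept).
#
# Data are generated from the model
#   y_gjk = delta_gj + s_k + e_gjk,
# with subject intercepts s_k ~ N(0, sigma_s^2) and residuals
# e ~ N(0, sigma_e^2), scaled so sigma_s^2 + sigma_e^2 = 1; the
# within-subject correlation is sigma_s^2. The planted interaction effect
# is expressed as Cohen's f relative to the (unit) within-cell population
# sd: f = sqrt(mean(delta^2)) for a pure (doubly centred) interaction
# pattern. Because the interaction test's error term is the residual
# variance only, power at fixed f rises steeply with the within-subject
# correlation, which is therefore an explicit parameter rather than a
# hidden constant.

#' Configuration for power / family-wise-error simulations
#'
#' @param effect_size_f Cohen's f of the planted age-by-ROI interaction,
#'   relative to the unit within-cell population sd (0 for the global
#'   null). The default 0.1 is a conventional smallest effect size of
#'   interest.
#' @param n_per_group participants per age group (default 40, i.e. a total
#'   sample of 80 for two groups).
#' @param n_groups number of age groups (default 2).
#' @param n_roi_levels number of ROI levels (default 3).
#' @param within_subject_correlation correlation between measurements of
#'   the same participant (the subject-intercept share of unit total
#'   variance), in `[0, 1)`. The default 0.75 is the value at which a
#'   two-group, three-ROI design with 40 participants per group reaches
#'   power 0.8 for an interaction of f = 0.1.
#' @param n_reps Monte-Carlo replicates.
#' @param alpha significance level.
#' @param seed integer seed.
#' @return A list of class `"power_sim_config"`.
#' @export
power_sim_config <- function(effect_size_f = 0.1, n_per_group = 40L,
                             n_groups = 2L, n_roi_levels = 3L,
                             within_subject_correlation = 0.75,
                             n_reps = 1000L, alpha = 0.05, seed = 1L) {
  stopifnot(effect_size_f >= 0, n_per_group >= 2L, n_groups >= 1L,
            n_roi_levels >= 2L, n_reps >= 1L, alpha > 0, alpha < 1)
  if (within_subject_correlation < 0 || within_subject_correlation >= 1) {
    stopf("within_subject_correlation must lie in [0, 1)")
  }
  structure(list(effect_size_f = effect_size_f,
                 n_per_group = as.integer(n_per_group),
                 n_groups = as.integer(n_groups),
                 n_roi_levels = as.integer(n_roi_levels),
                 within_subject_correlation = within_subject_correlation,
                 n_reps = as.integer(n_reps), alpha = alpha,
                 seed = as.integer(seed)),
            class = "power_sim_config")
}

# Doubly centred interaction pattern scaled to Cohen's f (relative to the
# unit within-cell sd).
interaction_effects <- function(g, r, f) {
  if (f == 0) return(matrix(0, g, r))
  gl <- seq_len(g) - mean(seq_len(g))
  rl <- seq_len(r) - mean(seq_len(r))
  p <- outer(gl, rl)
  p * f / sqrt(mean(p^2))
}

# One simulated balanced similarity table as a subjects x ROI matrix plus
# group labels; returned as the tidy table fit_mixed_model() consumes.
simulate_similarity_table <- function(config, delta = NULL) {
  g <- config$n_groups
  r <- config$n_roi_levels
  n <- config$n_per_group
  N <- g * n
  sigma_s <- sqrt(config$within_subject_correlation)
  sigma_e <- sqrt(1 - config$within_subject_correlation)
  if (is.null(delta)) {
    delta <- interaction_effects(g, r, config$effect_size_f)
  }
  grp <- rep(seq_len(g), each = n)
  y <- delta[grp, , drop = FALSE] +
    stats::rnorm(N, sd = sigma_s) +
    matrix(stats::rnorm(N * r, sd = sigma_e), N, r)
  data.frame(
    participant_id = rep(sprintf("s%03d", seq_len(N)), times = r),
    age_group = rep(sprintf("g%d", grp), times = r),
    roi_id = rep(sprintf("roi%d", seq_len(r)), each = N),
    rho = as.vector(y), stringsAsFactors = FALSE
  )
}

#' Family-wise error rate of the Holm-corrected ROI contrasts
#'
#' Simulates balanced datasets under the global null (no fixed effects),
#' fits the mixed model to each, forms the within-age-group pairwise ROI
#' contrasts on estimated marginal means, applies the Holm step-down
#' correction within each group, and records false rejections. The Holm
#' correction is applied *within* each age group, so the error rate it
#' controls is per correction family: `family = "per_group"` (the default)
#' estimates the probability that a given group's contrast family contains
#' at least one false rejection, which is the quantity controlled at
#' `alpha`. `family = "any_group"` instead records whether *any* contrast
#' across all groups is falsely rejected in a replicate; with two
#' independent families that union event approaches `1 - (1 - alpha)^2`
#' and is not controlled at `alpha` by construction.
#'
#' @param config a [power_sim_config()] with `effect_size_f = 0` and
#'   `n_reps >= 1000`.
#' @param family scope of the error event: `"per_group"` or `"any_group"`.
#' @return A list of class `"fwer_sim"`: `fwer`, `se`, `ci` (binomial 95%
#'   CI), `n_families`, `n_reps`, `alpha`, `family`, `config`.
#' @export
simulate_fwer <- function(config, family = c("per_group", "any_group")) {
  family <- match.arg(family)
  stopifnot(inherits(config, "power_sim_config"))
  if (config$effect_size_f != 0) {
    stopf("simulate_fwer requires effect_size_f = 0; use simulate_power")
  }
  if (config$n_reps < 1000L) stopf("insufficient replicates (need >= 1000)")
  hits <- with_seed(config$seed, {
    lapply(seq_len(config$n_reps), function(i) {
      tab <- simulate_similarity_table(config)
      fit <- fit_mixed_model(tab, method = "anova")
      ph <- posthoc_roi_contrasts(fit, alpha = config$alpha)
      tapply(ph$significant, ph$age_group, any)
    })
  })
  events <- if (family == "per_group") {
    unlist(hits)                       # one event per replicate x group
  } else {
    vapply(hits, any, NA)              # one event per replicate
  }
  p <- mean(events)
  se <- sqrt(p * (1 - p) / length(events))
  structure(list(fwer = p, se = se,
                 ci = c(max(0, p - 1.96 * se), min(1, p + 1.96 * se)),
                 n_families = length(events), n_reps = config$n_reps,
                 alpha = config$alpha, family = family, config = config),
            class = "fwer_sim")
}

#' @export
print.fwer_sim <- function(x, ...) {
  cat(sprintf(
    "Empirical FWER (%s): %.4f (SE %.4f, 95%% CI [%.4f, %.4f], %d reps, alpha %.2f)\n",
    x$family, x$fwer, x$se, x$ci[1L], x$ci[2L], x$n_reps, x$alpha))
  invisible(x)
}

#' Power of the age-by-ROI interaction test
#'
#' Simulates balanced datasets with a planted pure interaction of the
#' configured Cohen's f, fits the mixed model, and reports the fraction of
#' replicates in which the interaction F test rejects at `alpha`.
#'
#' @param config a [power_sim_config()] with `effect_size_f > 0`.
#' @return A list of class `"power_sim"`: `power`, `se`, `n_reps`, and the
#'   full generator configuration (power depends on every one of its
#'   parameters, particularly the within-subject correlation).
#' @export
simulate_power <- function(config) {
  stopifnot(inherits(config, "power_sim_config"))
  if (config$effect_size_f == 0) {
    stopf("effect_size_f = 0 is the global null: use simulate_fwer")
  }
  if (config$n_groups < 2L) stopf("interaction power needs >= 2 groups")
  rej <- with_seed(config$seed, {
    vapply(seq_len(config$n_reps), function(i) {
      tab <- simulate_similarity_table(config)
      fit <- fit_mixed_model(tab, method = "anova")
      a <- fit$anova_table
      a$p[a$effect == "age:roi"] < config$alpha
    }, NA)
  })
  p <- mean(rej)
  structure(list(power = p, se = sqrt(p * (1 - p) / config$n_reps),
                 n_reps = config$n_reps, alpha = config$alpha,
                 config = config),
            class = "power_sim")
}

#' @export
print.power_sim <- function(x, ...) {
  cat(sprintf(
    "Empirical power: %.3f (SE %.3f, %d reps, f = %.2f, n/group = %d, r_w = %.2f)\n",
    x$power, x$se, x$n_reps, x$config$effect_size_f,
    x$config$n_per_group, x$config$within_subject_correlation))
  invisible(x)
}

#' Power curves over sample size and effect size (common random numbers)
#'
#' Re-evaluates interaction power over a grid of per-group sample sizes
#' and/or effect sizes while reusing the same random draws across grid
#' points (subsetting subjects for smaller n, rescaling the planted effect
#' for different f), so the estimated power is monotone in both arguments
#' up to Monte-Carlo noise on shared replicates.
#'
#' @param config a [power_sim_config()]; its `n_per_group` must be the
#'   maximum of `n_values`.
#' @param n_values per-group sample sizes to evaluate.
#' @param f_values effect sizes to evaluate.
#' @return Data frame with columns `n_per_group`, `effect_size_f`, `power`.
#' @export
simulate_power_curve <- function(config, n_values = config$n_per_group,
                                 f_values = config$effect_size_f) {
  stopifnot(inherits(config, "power_sim_config"))
  if (max(n_values) != config$n_per_group) {
    stopf("config$n_per_group must equal max(n_values)")
  }
  if (any(f_values <= 0)) stopf("effect sizes must be positive")
  g <- config$n_groups
  r <- config$n_roi_levels
  n_max <- config$n_per_group
  sigma_e <- sqrt(1 - config$within_subject_correlation)
  base <- interaction_effects(g, r, 1)  # unit-f pattern
  rej <- array(0, c(length(n_values), length(f_values)))
  with_seed(config$seed, {
    for (rep in seq_len(config$n_reps)) {
      grp <- rep(seq_len(g), each = n_max)
      noise <- stats::rnorm(g * n_max, sd = sqrt(
        config$within_subject_correlation)) +
        matrix(stats::rnorm(g * n_max * r, sd = sigma_e), g * n_max, r)
      for (ni in seq_along(n_values)) {
        keep <- as.vector(vapply(seq_len(g), function(gi) {
          which(grp == gi)[seq_len(n_values[ni])]
        }, integer(n_values[ni])))
        for (fi in seq_along(f_values)) {
          y <- f_values[fi] * base[grp[keep], , drop = FALSE] +
            noise[keep, , drop = FALSE]
          N <- length(keep)
          tab <- data.frame(
            participant_id = rep(sprintf("s%03d", seq_len(N)), times = r),
            age_group = rep(sprintf("g%d", grp[keep]), times = r),
            roi_id = rep(sprintf("roi%d", seq_len(r)), each = N),
            rho = as.vector(y), stringsAsFactors = FALSE
          )
          fit <- fit_mixed_model(tab, method = "anova")
          a <- fit$anova_table
          if (a$p[a$effect == "age:roi"] < config$alpha) {
            rej[ni, fi] <- rej[ni, fi] + 1
          }
        }
      }
    }
  })
  out <- expand.grid(n_per_group = n_values, effect_size_f = f_values)
  out$power <- as.vector(rej) / config$n_reps
  out
}
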