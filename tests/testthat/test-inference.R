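# Mixed model fitting, estimated marginal means, post hoc contrasts.

test_that("mixed model F tests match the classical aov decomposition", {
  cell <- matrix(c(0.1, 0.05, 0.0, 0.42, 0.30, 0.22), 2, 3, byrow = TRUE)
  tab <- make_balanced_table(n_per_group = 10L, cell_means = cell,
                             sigma_s = 0.5, sigma_e = 0.3, seed = 3)
  oracle <- aov_mixed_oracle(tab)
  for (method in c("lmm", "anova")) {
    fit <- fit_mixed_model(tab, method = method)
    a <- fit$anova_table
    expect_equal(a$F[a$effect == "age"], unname(oracle$age["F"]),
                 tolerance = 1e-6)
    expect_equal(a$F[a$effect == "roi"], unname(oracle$roi["F"]),
                 tolerance = 1e-6)
    expect_equal(a$F[a$effect == "age:roi"],
                 unname(oracle$interaction["F"]), tolerance = 1e-6)
    expect_equal(a$df2[a$effect == "age"], oracle$df_between_resid,
                 tolerance = 1e-6)
    expect_equal(a$df2[a$effect == "age:roi"], oracle$df_within_resid,
                 tolerance = 1e-6)
    expect_equal(a$p[a$effect == "age:roi"],
                 unname(oracle$interaction["p"]), tolerance = 1e-6)
  }
})

test_that("single-group models drop the age factor and still match aov", {
  tab <- make_balanced_table(n_per_group = 12L, groups = "adult",
                             cell_means = matrix(c(0.2, 0.1, 0), 1, 3),
                             seed = 8)
  oracle <- aov_mixed_oracle(tab)
  for (method in c("lmm", "anova")) {
    fit <- fit_mixed_model(tab, method = method)
    expect_equal(fit$anova_table$effect, "roi")
    expect_equal(fit$anova_table$F, unname(oracle$roi["F"]),
                 tolerance = 1e-6)
    expect_equal(fit$anova_table$df2, oracle$df_within_resid,
                 tolerance = 1e-6)
  }
})

test_that("model input validation catches malformed tables", {
  tab <- make_balanced_table(seed = 1)
  expect_error(fit_mixed_model(tab[, 1:3]), "missing column")
  one_roi <- tab[tab$roi_id == "roi1", ]
  expect_error(fit_mixed_model(one_roi), "at least 2 ROI levels")
  bad <- tab
  bad$rho[1] <- NA
  expect_error(fit_mixed_model(bad), "non-finite")
  # unbalanced data are fine for lmm but rejected by the closed form
  unb <- tab[-1, ]
  expect_error(fit_mixed_model(unb, method = "anova"),
               "one row per participant x ROI")
  expect_s3_class(fit_mixed_model(unb, method = "lmm"), "rsa_mixed_model")
})

test_that("EMMs equal raw cell means on balanced data and shift with it", {
  cell <- matrix(c(0.2, 0.0, -0.1, 0.1, 0.15, 0.05), 2, 3, byrow = TRUE)
  tab <- make_balanced_table(n_per_group = 8L, cell_means = cell, seed = 5)
  raw <- aggregate(rho ~ age_group + roi_id, data = tab, mean)
  for (method in c("lmm", "anova")) {
    emm <- estimated_marginal_means(fit_mixed_model(tab, method = method))
    m <- merge(emm, raw, by = c("age_group", "roi_id"))
    expect_equal(m$emmean, m$rho, tolerance = 1e-10)
    expect_true(all(m$lower <= m$emmean & m$emmean <= m$upper))
    # excludes-zero flag is exactly the CI criterion
    expect_equal(m$excludes_zero, m$lower > 0 | m$upper < 0)
  }
  shifted <- tab
  shifted$rho <- shifted$rho + 0.37
  e0 <- estimated_marginal_means(fit_mixed_model(tab))
  e1 <- estimated_marginal_means(fit_mixed_model(shifted))
  expect_equal(e1$emmean, e0$emmean + 0.37, tolerance = 1e-8)
})

test_that("closed-form and lmer routes agree on EMMs and contrasts", {
  tab <- make_balanced_table(n_per_group = 9L,
                             cell_means = matrix(c(0.1, 0, 0, 0, 0.1, 0),
                                                 2, 3, byrow = TRUE),
                             seed = 11)
  f1 <- fit_mixed_model(tab, method = "lmm")
  f2 <- fit_mixed_model(tab, method = "anova")
  key <- function(d) d[order(d$age_group, d$roi_id), ]
  e1 <- key(estimated_marginal_means(f1))
  e2 <- key(estimated_marginal_means(f2))
  expect_equal(e1$emmean, e2$emmean, tolerance = 1e-8)
  expect_equal(e1$se, e2$se, tolerance = 1e-6)
  expect_equal(e1$df, e2$df, tolerance = 1e-3)
  pkey <- function(d) d[order(d$age_group, d$contrast), ]
  p1 <- pkey(posthoc_roi_contrasts(f1))
  p2 <- pkey(posthoc_roi_contrasts(f2))
  expect_equal(abs(p1$t), abs(p2$t), tolerance = 1e-6)
  expect_equal(p1$df, p2$df, tolerance = 1e-3)
  expect_equal(p1$p_holm, p2$p_holm, tolerance = 1e-6)
  b1 <- between_age_contrasts(f1)
  b2 <- between_age_contrasts(f2)
  expect_equal(b1$estimate[order(b1$roi_id)], b2$estimate[order(b2$roi_id)],
               tolerance = 1e-8)
  expect_equal(abs(b1$t[order(b1$roi_id)]), abs(b2$t[order(b2$roi_id)]),
               tolerance = 1e-5)
})

test_that("Holm adjustment follows the step-down enumeration", {
  expect_equal(holm_adjust(c(0.010, 0.020, 0.030)), c(0.030, 0.040, 0.040))
  expect_true(all(holm_adjust(c(0.010, 0.020, 0.030)) < 0.05))
  expect_equal(holm_adjust(c(0.020, 0.040, 0.300)), c(0.060, 0.080, 0.300))
  expect_false(any(holm_adjust(c(0.020, 0.040, 0.300)) < 0.05))
  expect_equal(holm_adjust(0.2), 0.2)
  expect_error(holm_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
  p <- c(0.001, 0.04, 0.2, 0.6)
  h <- holm_adjust(p)
  expect_true(all(h >= p))
  expect_true(all(diff(h[order(p)]) >= 0))
})

test_that("between-age contrasts are antisymmetric in group labels", {
  cell <- matrix(c(0, 0, 0, 1.0, 0, 0), 2, 3, byrow = TRUE)
  tab <- make_balanced_table(n_per_group = 12L, cell_means = cell,
                             sigma_s = 0.3, sigma_e = 0.2, seed = 2)
  fit <- fit_mixed_model(tab, method = "anova")
  b <- between_age_contrasts(fit)
  swapped <- tab
  swapped$age_group <- ifelse(tab$age_group == "young", "old", "young")
  bs <- between_age_contrasts(fit_mixed_model(swapped, method = "anova"))
  expect_equal(b$t[order(b$roi_id)], -bs$t[order(bs$roi_id)],
               tolerance = 1e-10)
  # planted old > young difference in roi1 is detected with positive t
  expect_gt(b$t[b$roi_id == "roi1"], 0)
  expect_error(between_age_contrasts(
    fit_mixed_model(make_balanced_table(groups = "adult", seed = 1))),
    "single age group")
})

test_that("between-age null t statistics are centred at zero", {
  set.seed(77)
  ts <- replicate(150, {
    tab <- make_balanced_table(n_per_group = 8L, seed = sample.int(1e6, 1))
    b <- between_age_contrasts(fit_mixed_model(tab, method = "anova"))
    b$t[1]
  })
  expect_lt(abs(mean(ts)), 3 / sqrt(150))
})

test_that("simulation harnesses validate their configurations", {
  expect_error(simulate_fwer(power_sim_config(effect_size_f = 0.1,
                                              n_reps = 2000)),
               "requires effect_size_f = 0")
  expect_error(simulate_fwer(power_sim_config(effect_size_f = 0,
                                              n_reps = 10)),
               "insufficient replicates")
  expect_error(simulate_power(power_sim_config(effect_size_f = 0)),
               "use simulate_fwer")
  expect_error(power_sim_config(within_subject_correlation = 1),
               "\\[0, 1\\)")
})

test_that("interaction power rises with sample size and effect size", {
  pc <- simulate_power_curve(
    power_sim_config(effect_size_f = 0.4, n_per_group = 40L,
                     n_reps = 150L, seed = 12),
    n_values = c(10L, 20L, 40L), f_values = c(0.15, 0.25, 0.4))
  byf <- split(pc, pc$effect_size_f)
  for (b in byf) {
    expect_true(all(diff(b$power[order(b$n_per_group)]) >= 0))
  }
  byn <- split(pc, pc$n_per_group)
  for (b in byn) {
    expect_true(all(diff(b$power[order(b$effect_size_f)]) >= 0))
  }
})

test_that("FWER control also holds at a stricter alpha", {
  f <- simulate_fwer(power_sim_config(effect_size_f = 0, n_reps = 1000L,
                                      alpha = 0.01, seed = 4))
  expect_lte(f$fwer, 0.01 + 2 * max(f$se, sqrt(0.01 * 0.99 / f$n_families)))
})
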