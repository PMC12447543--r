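# Independent oracles used to validate package computations. These are
# deliberately naive (brute-force) implementations kept separate from the
# package code paths they check.

# Dense zero-padded Gaussian convolution of a sparse count image: for each
# nonzero input cell, add its full 2-D Gaussian (normalized by the infinite
# discrete mass) over every output pixel.
dense_gauss_oracle <- function(counts, sigma) {
  H <- nrow(counts)
  W <- ncol(counts)
  r <- max(H, W, ceiling(12 * sigma))
  z <- sum(exp(-(seq.int(-r, r))^2 / (2 * sigma^2)))
  out <- matrix(0, H, W)
  nz <- which(counts != 0, arr.ind = TRUE)
  for (k in seq_len(nrow(nz))) {
    i0 <- nz[k, 1L]
    j0 <- nz[k, 2L]
    wi <- exp(-((seq_len(H) - i0)^2) / (2 * sigma^2)) / z
    wj <- exp(-((seq_len(W) - j0)^2) / (2 * sigma^2)) / z
    out <- out + counts[i0, j0] * outer(wi, wj)
  }
  out
}

# Pearson correlation from the raw-score formula.
pearson_hand <- function(x, y) {
  n <- length(x)
  sxy <- sum(x * y) - n * mean(x) * mean(y)
  sxx <- sum(x^2) - n * mean(x)^2
  syy <- sum(y^2) - n * mean(y)^2
  sxy / sqrt(sxx * syy)
}

# Spearman rho as rank-then-Pearson.
spearman_oracle <- function(x, y) pearson_hand(rank(x), rank(y))

# Textbook first-order partial correlation.
partial_formula <- function(rxy, rxz, ryz) {
  (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
}

# Classical mixed-design ANOVA via base aov() error strata: an established
# independent route to the balanced decomposition.
aov_mixed_oracle <- function(tab) {
  tab$age_group <- factor(tab$age_group)
  tab$roi_id <- factor(tab$roi_id)
  tab$participant_id <- factor(tab$participant_id)
  two_way <- nlevels(tab$age_group) >= 2L
  form <- if (two_way) {
    rho ~ age_group * roi_id + Error(participant_id)
  } else {
    rho ~ roi_id + Error(participant_id)
  }
  s <- summary(stats::aov(form, data = tab))
  between <- as.data.frame(s[["Error: participant_id"]][[1L]])
  within <- as.data.frame(s[["Error: Within"]][[1L]])
  clean <- function(d) {
    d$term <- trimws(rownames(d))
    d
  }
  between <- clean(between)
  within <- clean(within)
  grab <- function(d, term) {
    r <- d[d$term == term, ]
    c(F = r$`F value`, df1 = r$Df, p = r$`Pr(>F)`)
  }
  if (two_way) {
    list(age = grab(between, "age_group"),
         roi = grab(within, "roi_id"),
         interaction = grab(within, "age_group:roi_id"),
         df_between_resid = between$Df[between$term == "Residuals"],
         df_within_resid = within$Df[within$term == "Residuals"])
  } else {
    list(roi = grab(within, "roi_id"),
         df_within_resid = within$Df[within$term == "Residuals"])
  }
}

# Balanced similarity table with planted cell means and subject variance.
make_balanced_table <- function(n_per_group = 12L, groups = c("young", "old"),
                                rois = c("roi1", "roi2", "roi3"),
                                cell_means = NULL, sigma_s = 0.6,
                                sigma_e = 0.4, seed = 1L) {
  g <- length(groups)
  r <- length(rois)
  N <- g * n_per_group
  if (is.null(cell_means)) cell_means <- matrix(0, g, r)
  set.seed(seed)
  grp <- rep(seq_len(g), each = n_per_group)
  y <- cell_means[grp, , drop = FALSE] + rnorm(N, sd = sigma_s) +
    matrix(rnorm(N * r, sd = sigma_e), N, r)
  data.frame(
    participant_id = rep(sprintf("s%03d", seq_len(N)), times = r),
    age_group = rep(groups[grp], times = r),
    roi_id = rep(rois, each = N),
    rho = as.vector(y), stringsAsFactors = FALSE
  )
}
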