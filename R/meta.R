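#' Bonferroni-adjusted significance threshold
#'
#' With the seven structures tested, alpha = 0.05/7, conventionally reported
#' as 0.007.
#'
#' @param n_tests number of tests (default 7).
#' @return Adjusted alpha.
#' @export
bonferroni_alpha <- function(n_tests = 7) {
  if (n_tests < 1) stop("n_tests must be >= 1")
  0.05 / n_tests
}

#' Apply the meta-analysis inclusion filters
#'
#' Keeps datasets where every group of the requested contrast has at least
#' `min_per_group` observations; the age contrast additionally requires an
#' age interquartile range of at least `min_iqr_years` (so that a linear
#' per-year coefficient is estimable from real age spread) together with the
#' per-sex minimum.
#'
#' @param summaries dataset-summary data.frame (rows for one structure).
#' @param contrast one of "sex", "handedness", "age", "lateralization_male",
#'   "lateralization_female".
#' @param min_per_group minimum group size (default 15).
#' @param min_iqr_years minimum age IQR width for the age contrast; set to
#'   NULL to disable.
#' @return The included subset of `summaries`.
#' @export
filter_datasets <- function(summaries, contrast, min_per_group = 15,
                            min_iqr_years = 5) {
  keep <- switch(contrast,
    sex = summaries$n_male >= min_per_group & summaries$n_female >= min_per_group,
    handedness = summaries$n_left >= min_per_group & summaries$n_right >= min_per_group,
    age = {
      k <- summaries$n_male >= min_per_group & summaries$n_female >= min_per_group
      if (!is.null(min_iqr_years)) k <- k & summaries$age_iqr >= min_iqr_years
      k
    },
    lateralization_male = summaries$n_male >= min_per_group,
    lateralization_female = summaries$n_female >= min_per_group,
    stop("unknown contrast: ", contrast))
  keep[is.na(keep)] <- FALSE
  out <- summaries[keep, , drop = FALSE]
  if (nrow(out) == 0L)
    stop("no datasets pass the ", contrast, " inclusion filter ",
         "(min_per_group = ", min_per_group,
         if (contrast == "age" && !is.null(min_iqr_years))
           paste0(", min_iqr_years = ", min_iqr_years) else "", ")")
  out
}

#' DerSimonian-Laird random-effects pooling
#'
#' Inverse-variance pooling with a moment estimate of the between-study
#' variance: fixed weights \eqn{w_i = 1/se_i^2}, Cochran's
#' \eqn{Q = \sum w_i (y_i - \bar y_w)^2},
#' \eqn{\tau^2 = \max(0, (Q - (k-1)) / (\sum w - \sum w^2/\sum w))}, then
#' random-effects weights \eqn{w_i^* = 1/(se_i^2 + \tau^2)}. The pooled
#' p-value uses the normal approximation on z. Heterogeneity is summarised by
#' Q (with a chi-squared p on k-1 df) and Higgins' I-squared.
#'
#' @param y per-dataset effects.
#' @param se per-dataset standard errors (> 0).
#' @param n optional per-dataset total Ns (summed into `total_n`).
#' @return An object of class `meta_result`: list with `pooled`, `se`, `z`,
#'   `p`, `tau2`, `Q`, `Q_df`, `Q_p`, `I2`, `k`, `total_n`, plus per-study
#'   `y`, `se_i`, `weights` (random-effects, normalised).
#' @export
random_effects_pool <- function(y, se, n = NULL) {
  if (length(y) != length(se)) stop("y and se must have equal length")
  ok <- is.finite(y) & is.finite(se)
  if (!all(ok)) { y <- y[ok]; se <- se[ok]; if (!is.null(n)) n <- n[ok] }
  k <- length(y)
  if (k < 2L) stop("need at least 2 datasets to pool")
  if (any(se <= 0)) stop("all standard errors must be positive")
  w <- 1 / se^2
  yw <- sum(w * y) / sum(w)
  Q <- sum(w * (y - yw)^2)
  tau2 <- max(0, (Q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))
  ws <- 1 / (se^2 + tau2)
  pooled <- sum(ws * y) / sum(ws)
  se_p <- 1 / sqrt(sum(ws))
  z <- pooled / se_p
  structure(list(
    pooled = pooled, se = se_p, z = z, p = 2 * stats::pnorm(-abs(z)),
    tau2 = tau2, Q = Q, Q_df = k - 1L,
    Q_p = stats::pchisq(Q, df = k - 1, lower.tail = FALSE),
    I2 = higgins_i2(Q, k), k = k,
    total_n = if (is.null(n)) NA_integer_ else sum(n),
    y = y, se_i = se, weights = ws / sum(ws)
  ), class = "meta_result")
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf("Random-effects meta-analysis (k = %d%s)\n", x$k,
              if (is.na(x$total_n)) "" else sprintf(", N = %d", x$total_n)))
  cat(sprintf("  pooled effect %.4g (SE %.3g), z = %.3f, p = %.3g\n",
              x$pooled, x$se, x$z, x$p))
  cat(sprintf("  tau^2 = %.3g; Q = %.2f on %d df (p = %.3g); I^2 = %.1f%%\n",
              x$tau2, x$Q, x$Q_df, x$Q_p, x$I2))
  invisible(x)
}

#' Higgins' I-squared heterogeneity percentage
#'
#' The share of variability in observed effects beyond what sampling error
#' alone would produce: max(0, (Q - (k-1))/Q) * 100. Zero whenever Q falls
#' at or below its degrees of freedom.
#'
#' @param Q Cochran's Q statistic (>= 0).
#' @param k number of datasets (>= 2).
#' @return Percentage in \[0, 100\].
#' @export
higgins_i2 <- function(Q, k) {
  if (any(Q < 0)) stop("Q must be non-negative")
  if (any(k < 2)) stop("k must be >= 2")
  ifelse(Q == 0, 0, pmax(0, (Q - (k - 1)) / Q) * 100)
}

#' Rosenberg's weighted fail-safe N
#'
#' The smallest number m of hypothetical null datasets — each contributing
#' effect zero with the mean observed fixed-effect weight — whose addition
#' raises the pooled fixed-effect two-sided p-value to `alpha` or above.
#' Interpreted as how many average null results would be needed to render
#' the finding non-significant. Returns 0 when the pooled p is already at or
#' above `alpha`.
#'
#' @param y per-dataset effects.
#' @param se per-dataset standard errors (> 0).
#' @param alpha significance threshold (default 0.007, the Bonferroni level
#'   for seven structures as conventionally reported).
#' @return Integer fail-safe count.
#' @export
rosenberg_failsafe <- function(y, se, alpha = 0.007) {
  if (any(se <= 0)) stop("all standard errors must be positive")
  w <- 1 / se^2
  S1 <- sum(w)
  Sy <- sum(w * y)
  wbar <- mean(w)
  pm <- function(m) 2 * stats::pnorm(-abs(Sy) / sqrt(S1 + m * wbar))
  if (pm(0) >= alpha) return(0L)
  # adding m null studies of weight wbar leaves sum(w*y) unchanged and grows
  # the pooled variance: z(m)^2 = Sy^2/(S1 + m*wbar); solve z(m) = z_crit
  zc <- stats::qnorm(1 - alpha / 2)
  m <- max(0, ceiling((Sy^2 / zc^2 - S1) / wbar))
  # guard against ties at the boundary under floating point
  while (m > 0 && pm(m - 1) >= alpha) m <- m - 1
  while (pm(m) < alpha) m <- m + 1
  as.integer(m)
}

#' Weighted meta-regression of age coefficients on median ages
#'
#' Post-hoc moderator analysis: regresses each dataset's per-year age
#' coefficient on the dataset's median age, weighting datasets by the square
#' root of their sample size. A nonzero slope indicates that the age effect
#' itself changes across the lifespan.
#'
#' @param coefs per-dataset age coefficients.
#' @param median_ages per-dataset median ages (years); must not all be equal.
#' @param n per-dataset sample sizes.
#' @return List with `slope`, `se`, `t`, `p`, `k`.
#' @export
weighted_meta_regression <- function(coefs, median_ages, n) {
  ok <- is.finite(coefs) & is.finite(median_ages) & is.finite(n)
  coefs <- coefs[ok]; median_ages <- median_ages[ok]; n <- n[ok]
  if (length(coefs) < 3L) stop("need at least 3 datasets")
  if (length(unique(median_ages)) < 2L) stop("all median ages are equal")
  fit <- stats::lm(coefs ~ median_ages, weights = sqrt(n))
  cf <- summary(fit)$coefficients
  list(slope = cf["median_ages", 1], se = cf["median_ages", 2],
       t = cf["median_ages", 3], p = cf["median_ages", 4], k = length(coefs))
}

#' Meta-analyse dataset summaries for one contrast
#'
#' Applies the inclusion filters, reconstructs standard errors from the
#' 95 % CI and Welch degrees of freedom where those crossed the site
#' boundary (sex and handedness contrasts), pools by DerSimonian-Laird, and
#' computes Rosenberg's fail-safe N when the pooled p falls below `alpha`.
#'
#' @param summaries dataset-summary data.frame from [site_summary()]
#'   (possibly several sites appended), all rows for all structures.
#' @param contrast "sex", "handedness", "age", "lateralization_male" or
#'   "lateralization_female".
#' @param structures structures to pool (default all present).
#' @param min_per_group,min_iqr_years inclusion filters, see
#'   [filter_datasets()].
#' @param alpha threshold used for fail-safe N (default 0.007).
#' @return A data.frame with one row per structure: pooled effect, se, z, p,
#'   tau2, Q, Q_p, I2, k, total_n, failsafe_n. Attribute `"per_site"` holds
#'   the per-dataset effects, CIs and weights (forest-plot export).
#' @export
meta_analyze <- function(summaries, contrast,
                         structures = unique(summaries$structure),
                         min_per_group = 15, min_iqr_years = 5,
                         alpha = 0.007) {
  rows <- list(); forest <- list()
  for (s in structures) {
    ss <- summaries[summaries$structure == s, , drop = FALSE]
    ss <- filter_datasets(ss, contrast, min_per_group, min_iqr_years)
    ex <- .extract_effect(ss, contrast)
    ok <- is.finite(ex$y) & is.finite(ex$se) & ex$se > 0
    ss <- ss[ok, , drop = FALSE]
    y <- ex$y[ok]; se <- ex$se[ok]; ntot <- ex$n[ok]
    if (length(y) < 2L)
      stop("fewer than 2 usable datasets for ", s, " / ", contrast)
    pool <- random_effects_pool(y, se, n = ntot)
    fsn <- if (pool$p < alpha) rosenberg_failsafe(y, se, alpha) else 0L
    rows[[s]] <- data.frame(
      structure = s, contrast = contrast, pooled = pool$pooled, se = pool$se,
      z = pool$z, p = pool$p, tau2 = pool$tau2, Q = pool$Q, Q_df = pool$Q_df,
      Q_p = pool$Q_p, I2 = pool$I2, k = pool$k, total_n = pool$total_n,
      failsafe_n = fsn, stringsAsFactors = FALSE)
    forest[[s]] <- data.frame(
      structure = s, site_id = ss$site_id, effect = y, se = se,
      ci_lo = y - 1.96 * se, ci_hi = y + 1.96 * se,
      weight = pool$weights, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "per_site") <- do.call(rbind, forest)
  out
}

# per-dataset effect, SE and total n for a contrast. Sex and handedness
# effects travel as CI + Welch df; the SE is reconstructed here.
.extract_effect <- function(ss, contrast) {
  switch(contrast,
    sex = list(y = ss$sex_diff,
               se = se_from_ci(ss$sex_ci_lo, ss$sex_ci_hi, ss$sex_df),
               n = ss$n_male + ss$n_female),
    handedness = list(y = ss$hand_diff,
                      se = se_from_ci(ss$hand_ci_lo, ss$hand_ci_hi, ss$hand_df),
                      n = ss$n_left + ss$n_right),
    age = list(y = ss$age_coef, se = ss$age_se, n = ss$n_male + ss$n_female),
    lateralization_male = list(y = ss$male_mean_ai, se = ss$male_se_ai,
                               n = ss$n_male),
    lateralization_female = list(y = ss$female_mean_ai, se = ss$female_se_ai,
                                 n = ss$n_female),
    stop("unknown contrast: ", contrast))
}

#' Meta-regression of age effects across all structures
#'
#' Convenience wrapper running [weighted_meta_regression()] per structure on
#' the age-filtered dataset summaries.
#'
#' @inheritParams meta_analyze
#' @return data.frame with one row per structure (slope, se, t, p, k).
#' @export
age_meta_regression <- function(summaries,
                                structures = unique(summaries$structure),
                                min_per_group = 15, min_iqr_years = 5) {
  rows <- lapply(structures, function(s) {
    ss <- summaries[summaries$structure == s, , drop = FALSE]
    ss <- filter_datasets(ss, "age", min_per_group, min_iqr_years)
    r <- weighted_meta_regression(ss$age_coef, ss$median_age,
                                  ss$n_male + ss$n_female)
    data.frame(structure = s, slope = r$slope, se = r$se, t = r$t, p = r$p,
               k = r$k, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
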