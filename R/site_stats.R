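#' Volumetric asymmetry index
#'
#' AI = (left - right) / (left + right): the relative volume difference of a
#' bilaterally paired structure, dimensionless in \[-1, 1\]. Positive values
#' mean the left structure is larger.
#'
#' @param left,right numeric vectors of left/right volumes (mm3), >= 0.
#' @return Numeric vector of asymmetry indices. Elements where either side is
#'   missing are NA.
#' @examples
#' compute_ai(110, 90)   # 0.1
#' compute_ai(100, 100)  # 0
#' @export
compute_ai <- function(left, right) {
  if (length(left) != length(right))
    stop("left and right must have equal length")
  ok <- !is.na(left) & !is.na(right)
  if (any(left[ok] < 0) || any(right[ok] < 0))
    stop("volumes must be non-negative")
  if (any((left[ok] + right[ok]) <= 0))
    stop("left + right must be positive wherever both sides are present")
  (left - right) / (left + right)
}

#' Adaptive SD threshold for outlier exclusion
#'
#' The outlier rule adapts to dataset size: smaller samples use a stricter
#' multiplier because extreme observations distort small-sample statistics
#' more. N < 150 gives 2.5; 150 <= N <= 1000 gives 3; N > 1000 gives 3.5.
#'
#' @param n sample size of the dataset (>= 1).
#' @return SD multiplier (2.5, 3 or 3.5).
#' @export
sd_threshold <- function(n) {
  if (!is.numeric(n) || length(n) != 1L || !is.finite(n) || n < 1)
    stop("n must be a single number >= 1")
  if (n < 150) 2.5 else if (n <= 1000) 3.0 else 3.5
}

#' Mean +/- k SD inclusion mask
#'
#' Flags values more than `threshold` standard deviations from the mean.
#' Mean and SD are computed once from all finite values (single,
#' non-iterative pass). Zero-variance input keeps everything. Missing values
#' are not flagged here; missingness is handled per structure by the caller.
#'
#' @param values numeric vector (>= 2 finite values).
#' @param threshold SD multiplier, e.g. from [sd_threshold()].
#' @return Logical vector, TRUE = keep.
#' @export
exclude_outliers <- function(values, threshold) {
  fin <- is.finite(values)
  if (sum(fin) < 2L) stop("need at least 2 finite values")
  m <- mean(values[fin])
  s <- stats::sd(values[fin])
  if (!is.finite(s) || s == 0) return(rep(TRUE, length(values)))
  keep <- abs(values - m) <= threshold * s
  keep[!fin] <- TRUE
  keep
}

#' OLS residualisation of a response on covariates
#'
#' Removes linear covariate effects (an intercept is always included) and
#' returns the residuals. Used to adjust asymmetry indices for age and ICV
#' (and sex, for handedness contrasts) before group comparisons.
#'
#' @param y numeric response vector.
#' @param covariates numeric matrix or data.frame, one row per element of y.
#' @return Residual vector; mean zero to machine precision.
#' @export
residualize <- function(y, covariates) {
  X <- as.matrix(covariates)
  storage.mode(X) <- "double"
  if (nrow(X) != length(y)) stop("covariates must have one row per observation")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  D <- cbind(`(intercept)` = 1, X)
  qd <- qr(D)
  if (qd$rank < ncol(D)) {
    bad <- colnames(D)[qd$pivot[(qd$rank + 1L):ncol(D)]]
    stop("rank-deficient design; collinear column(s): ", paste(bad, collapse = ", "))
  }
  as.vector(qr.resid(qd, y))
}

#' Welch two-sample t-test
#'
#' Group comparison without assuming equal variances or balanced sizes
#' (Satterthwaite degrees of freedom). The reported difference is
#' `mean(a) - mean(b)`.
#'
#' @param a,b numeric vectors (each n >= 2).
#' @param conf.level confidence level of the interval.
#' @return List with `mean_diff`, `se`, `t`, `df`, `p`, `ci` (2-vector),
#'   `n_a`, `n_b`.
#' @export
welch_test <- function(a, b, conf.level = 0.95) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 2L || length(b) < 2L) stop("each group needs >= 2 observations")
  if (stats::var(a) == 0 && stats::var(b) == 0)
    stop("degenerate input: both groups have zero variance")
  ht <- stats::t.test(a, b, var.equal = FALSE, conf.level = conf.level)
  md <- unname(ht$estimate[1] - ht$estimate[2])
  list(mean_diff = md,
       se = unname(ht$stderr),
       t = unname(ht$statistic),
       df = unname(ht$parameter),
       p = ht$p.value,
       ci = unname(ht$conf.int),
       n_a = length(a), n_b = length(b))
}

#' Per-year age coefficient on the asymmetry index (ANCOVA)
#'
#' Fits AI ~ age + sex + ICV by ordinary least squares and reports the age
#' coefficient, its standard error and two-sided p-value.
#'
#' @param ai numeric AI vector.
#' @param age numeric, years.
#' @param sex factor or character (two levels) or numeric indicator.
#' @param icv numeric, mm3.
#' @return List with `age_coef`, `se`, `p`, `n`.
#' @export
ancova_age <- function(ai, age, sex, icv) {
  if (length(unique(age[is.finite(age)])) < 2L) stop("age is constant")
  sexn <- if (is.numeric(sex)) sex else as.numeric(factor(sex)) - 1
  fit <- stats::lm(ai ~ age + sexn + icv)
  cf <- summary(fit)$coefficients
  if (!"age" %in% rownames(cf)) stop("age dropped from the model (collinear design)")
  list(age_coef = cf["age", 1], se = cf["age", 2], p = cf["age", 4],
       n = length(fit$residuals))
}

#' One-sample lateralization test
#'
#' Tests whether the mean asymmetry index differs from zero, the point of
#' volumetric symmetry. Run separately per sex by the site summary stage.
#'
#' @param ai numeric AI vector, n >= 2, nonzero variance.
#' @return List with `mean`, `sd`, `se`, `t`, `df`, `p`, `n`.
#' @export
one_sample_lateralization <- function(ai) {
  ai <- ai[is.finite(ai)]
  if (length(ai) < 2L) stop("need >= 2 observations")
  if (stats::var(ai) == 0) stop("zero variance")
  ht <- stats::t.test(ai, mu = 0)
  list(mean = unname(ht$estimate), sd = stats::sd(ai),
       se = unname(ht$stderr), t = unname(ht$statistic),
       df = unname(ht$parameter), p = ht$p.value, n = length(ai))
}

#' Standard error from a 95 % confidence interval
#'
#' Inverts the t-based interval: se = (upper - lower) / (2 * t_{0.975, df}).
#' Used at the site-to-meta boundary, where Welch contrasts travel as
#' CI + degrees of freedom and the pooling stage reconstructs the SE.
#'
#' @param lower,upper interval endpoints (upper > lower).
#' @param df degrees of freedom (>= 1; Welch df may be fractional).
#' @return Standard error.
#' @export
se_from_ci <- function(lower, upper, df) {
  if (any(df < 1, na.rm = TRUE)) stop("df must be >= 1")
  if (any(upper <= lower, na.rm = TRUE)) stop("upper must exceed lower")
  (upper - lower) / (2 * stats::qt(0.975, df))
}

#' Within-site summary statistics for one subject table
#'
#' Runs the full within-dataset stage for each requested structure:
#' compute AIs, drop per-structure outliers by the adaptive SD rule (applied
#' jointly to the left volume, right volume and AI), then derive
#' \itemize{
#'   \item the Welch male-female contrast on AIs residualised for age and ICV,
#'   \item the Welch left-right-hander contrast on AIs residualised for age,
#'     ICV and sex,
#'   \item the ANCOVA per-year age coefficient (covariates sex and ICV),
#'   \item one-sample lateralization tests per sex on raw AIs.
#' }
#' Only these summary statistics cross the site boundary; subject-level data
#' never do.
#'
#' @param table a subject table (see [read_site_table()] for the schema).
#' @param site_id site label; defaults to the table's `site_id` attribute.
#' @param structures structures to summarise (default all seven).
#' @param keep_ai if TRUE, attach the post-exclusion AI vectors as attribute
#'   `"ai_records"` (needed by the variance-partition stage).
#' @return A data.frame with one row per structure (the dataset summary),
#'   plus attribute `"exclusions"` recording outlier counts.
#' @export
site_summary <- function(table, site_id = NULL, structures = ai_structures(),
                         keep_ai = FALSE) {
  validate_site_table(table, structures)
  if (is.null(site_id)) site_id <- attr(table, "site_id") %||% "site"
  version <- attr(table, "fs_version") %||%
    (if ("fs_version" %in% names(table)) as.character(table$fs_version[1]) else NA_character_)
  n_site <- nrow(table)
  thr <- sd_threshold(n_site)

  rows <- vector("list", length(structures))
  ai_records <- vector("list", length(structures))
  excl <- integer(length(structures))
  names(excl) <- structures

  for (si in seq_along(structures)) {
    s <- structures[si]
    L <- table[[paste0(s, "_L_mm3")]]
    R <- table[[paste0(s, "_R_mm3")]]
    avail <- !is.na(L) & !is.na(R) & (L + R) > 0
    sub <- table[avail, , drop = FALSE]
    L <- L[avail]; R <- R[avail]
    ai <- compute_ai(L, R)

    # joint outlier pass on the two volume columns and the AI
    if (length(ai) >= 2L) {
      keep <- exclude_outliers(L, thr) & exclude_outliers(R, thr) &
        exclude_outliers(ai, thr)
    } else keep <- rep(TRUE, length(ai))
    excl[si] <- sum(!keep)
    sub <- sub[keep, , drop = FALSE]
    ai <- ai[keep]

    male <- sub$sex == "M"
    cc <- is.finite(sub$age_years) & is.finite(sub$icv_mm3)

    row <- list(site_id = site_id, structure = s, n = length(ai),
                n_excluded = excl[si],
                n_male = sum(male, na.rm = TRUE),
                n_female = sum(!male, na.rm = TRUE),
                fs_version = version,
                median_age = stats::median(sub$age_years, na.rm = TRUE),
                age_iqr = unname(diff(stats::quantile(sub$age_years,
                                                      c(0.25, 0.75), na.rm = TRUE))))

    # sex contrast on residualised AI (age + ICV removed)
    sexres <- .try_contrast(ai[cc], male[cc],
                            cbind(age = sub$age_years[cc], icv = sub$icv_mm3[cc]),
                            min_n = 2L)
    row <- c(row, stats::setNames(sexres, paste0("sex_", names(sexres))))

    # handedness contrast on residualised AI (age + ICV + sex removed)
    hnd <- sub$handedness
    hc <- cc & !is.na(hnd)
    handres <- .try_contrast(ai[hc], hnd[hc] == "L",
                             cbind(age = sub$age_years[hc], icv = sub$icv_mm3[hc],
                                   sex = as.numeric(male[hc])),
                             min_n = 2L)
    row <- c(row, stats::setNames(handres, paste0("hand_", names(handres))))
    row$n_left <- sum(hnd == "L", na.rm = TRUE)
    row$n_right <- sum(hnd == "R", na.rm = TRUE)

    # age coefficient (ANCOVA with sex and ICV)
    agec <- tryCatch(
      ancova_age(ai[cc], sub$age_years[cc], as.numeric(male[cc]), sub$icv_mm3[cc]),
      error = function(e) list(age_coef = NA_real_, se = NA_real_, p = NA_real_,
                               n = NA_integer_))
    row$age_coef <- agec$age_coef; row$age_se <- agec$se; row$age_p <- agec$p

    # population-level lateralization per sex, on raw AIs
    for (sx in c("male", "female")) {
      v <- ai[if (sx == "male") male else !male]
      lt <- tryCatch(one_sample_lateralization(v),
                     error = function(e) list(mean = NA_real_, sd = NA_real_,
                                              se = NA_real_, t = NA_real_,
                                              df = NA_real_, p = NA_real_,
                                              n = length(v)))
      row[[paste0(sx, "_mean_ai")]] <- lt$mean
      row[[paste0(sx, "_sd_ai")]] <- lt$sd
      row[[paste0(sx, "_se_ai")]] <- lt$se
      row[[paste0(sx, "_t")]] <- lt$t
      row[[paste0(sx, "_p")]] <- lt$p
    }

    rows[[si]] <- as.data.frame(row, stringsAsFactors = FALSE)
    if (keep_ai)
      ai_records[[si]] <- data.frame(structure = s, ai = ai,
                                     site = site_id, version = version,
                                     stringsAsFactors = FALSE)
  }

  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "exclusions") <- excl
  if (keep_ai) attr(out, "ai_records") <- do.call(rbind, ai_records)
  out
}

# Welch contrast of group TRUE minus group FALSE on residualised values;
# returns NA fields when a group is too small or the design degenerate.
.try_contrast <- function(y, grp, covariates, min_n = 2L) {
  empty <- list(diff = NA_real_, se = NA_real_, t = NA_real_, df = NA_real_,
                p = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_,
                n1 = sum(grp, na.rm = TRUE), n2 = sum(!grp, na.rm = TRUE))
  if (length(y) < 4L || sum(grp) < min_n || sum(!grp) < min_n) return(empty)
  res <- tryCatch(residualize(y, covariates), error = function(e) NULL)
  if (is.null(res)) return(empty)
  wt <- tryCatch(welch_test(res[grp], res[!grp]), error = function(e) NULL)
  if (is.null(wt)) return(empty)
  list(diff = wt$mean_diff, se = wt$se, t = wt$t, df = wt$df, p = wt$p,
       ci_lo = wt$ci[1], ci_hi = wt$ci[2], n1 = wt$n_a, n2 = wt$n_b)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
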