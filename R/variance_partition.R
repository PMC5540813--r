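#' One-way eta-squared
#'
#' Share of total variance attributable to a grouping factor:
#' SS_between / SS_total from a one-way ANOVA decomposition.
#'
#' @param values numeric vector.
#' @param labels grouping labels (>= 2 non-empty groups).
#' @return Fraction in \[0, 1\].
#' @export
eta_squared <- function(values, labels) {
  ok <- is.finite(values) & !is.na(labels)
  values <- values[ok]; labels <- factor(labels[ok])
  labels <- droplevels(labels)
  if (nlevels(labels) < 2L) stop("need at least 2 groups")
  gm <- mean(values)
  sst <- sum((values - gm)^2)
  if (sst == 0) stop("zero total variance")
  means <- tapply(values, labels, mean)
  ns <- tabulate(labels)
  ssb <- sum(ns * (means - gm)^2)
  ssb / sst
}

#' Between-dataset and between-version heterogeneity of asymmetry indices
#'
#' For each structure, partitions the pooled post-exclusion AI variance into
#' a between-dataset and a between-software-version share (one-way
#' eta-squared per factor, main effects only: each site ran one segmentation
#' version, so the two factors are confounded and no interaction is
#' estimable). `sigma2_within` is the within-dataset ANOVA mean square,
#' i.e. the average AI variability after removing dataset mean differences.
#'
#' @param ai_records data.frame with columns `structure`, `ai`, `site`,
#'   `version` (as produced by [site_summary()] with `keep_ai = TRUE`,
#'   rows from all sites appended).
#' @return data.frame with one row per structure: `mean_ai`,
#'   `sigma2_within`, `n`, `eta2_dataset`, `eta2_version`.
#' @export
ai_heterogeneity <- function(ai_records) {
  need <- c("structure", "ai", "site", "version")
  if (!all(need %in% names(ai_records)))
    stop("ai_records must have columns ", paste(need, collapse = ", "))
  rows <- lapply(split(ai_records, ai_records$structure), function(d) {
    site <- factor(d$site)
    n <- nrow(d)
    k <- nlevels(droplevels(site))
    gm <- mean(d$ai)
    sst <- sum((d$ai - gm)^2)
    means <- tapply(d$ai, site, mean)
    ssb <- sum(tabulate(site) * (means - gm)^2)
    e2v <- if (length(unique(d$version[!is.na(d$version)])) >= 2L)
      eta_squared(d$ai, d$version) else NA_real_
    data.frame(structure = d$structure[1], mean_ai = gm,
               sigma2_within = (sst - ssb) / (n - k), n = n,
               eta2_dataset = ssb / sst, eta2_version = e2v,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(match(out$structure, ai_structures())), , drop = FALSE]
  rownames(out) <- NULL
  out
}
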