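#' Configuration for the multi-site volumetric simulator
#'
#' Describes the generative world the downstream stages assume: per-subject
#' asymmetry indices are
#' \deqn{AI = \mu_s + u_{site} + v_{version} + \gamma_s \cdot sex_c +
#'   \kappa_s (age - \bar a_{site}) + \epsilon,}
#' with Gaussian noise, a Gaussian site offset, a fixed offset per
#' segmentation-software version (one version per site), effect-coded sex
#' (+gamma/2 for males, -gamma/2 for females, so the male-minus-female
#' difference is gamma and the site mean stays at mu plus offsets), and age
#' centred at the site's mid-range. Each structure's total bilateral volume
#' is linear in ICV plus noise, then split as L = T(1+AI)/2, R = T(1-AI)/2.
#'
#' Per-structure defaults come from [reference_effects()]: mean AIs and
#' within-dataset variances, sex and age effects at consortium-scale
#' magnitudes, and site / version offset SDs calibrated so the
#' between-dataset and between-version variance shares match the reference
#' eta-squared columns (site_sd = sqrt(sigma2_within * eta2/(1 - eta2));
#' version offsets sized for a 75/25 split of sites across two versions).
#'
#' @param n_sites number of sites (default 52).
#' @param n_range inclusive range of per-site sample sizes (default 30-800).
#' @param sex_ratio fraction of males, in (0, 1).
#' @param age_low_range,age_span_range each site draws a uniform age window:
#'   lower bound from `age_low_range`, width from `age_span_range` (years).
#' @param icv_mean,icv_sd intracranial volume scale, mm3 (log-normal).
#' @param structures subset of [ai_structures()] to simulate.
#' @param mean_ai,ai_sd,sex_effect,age_effect,site_sd named per-structure
#'   overrides of the reference defaults (any subset).
#' @param version_labels software version labels; the first is the reference
#'   (offset 0).
#' @param version_offsets named list per structure of per-version offsets;
#'   default calibrated as described above.
#' @param version_ref_frac fraction of sites on the reference version.
#' @param left_frac fraction of left-handers (default 0.1); handedness is
#'   independent of AI.
#' @param hand_known_frac fraction of subjects with known handedness.
#' @param seed integer seed (mandatory).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_sites = 52, n_range = c(30, 800), sex_ratio = 0.5,
                       age_low_range = c(10, 55), age_span_range = c(8, 40),
                       icv_mean = 1.5e6, icv_sd = 1.5e5,
                       structures = ai_structures(),
                       mean_ai = NULL, ai_sd = NULL, sex_effect = NULL,
                       age_effect = NULL, site_sd = NULL,
                       version_labels = c("5.3", "5.1"),
                       version_offsets = NULL, version_ref_frac = 0.75,
                       left_frac = 0.1, hand_known_frac = 0.75,
                       seed) {
  if (missing(seed)) stop("seed is mandatory")
  ref <- reference_effects()
  ref <- ref[match(structures, ref$structure), , drop = FALSE]
  p <- data.frame(
    structure = structures,
    mean_ai = ref$mean_ai,
    ai_sd = sqrt(ref$sigma2_within),
    sex_effect = ref$sex_effect,
    age_effect = ref$age_effect,
    site_sd = sqrt(ref$sigma2_within * ref$eta2_dataset / (1 - ref$eta2_dataset)),
    mean_total = unname(.structure_volumes()[structures]),
    stringsAsFactors = FALSE)
  for (f in c("mean_ai", "ai_sd", "sex_effect", "age_effect", "site_sd")) {
    ov <- switch(f, mean_ai = mean_ai, ai_sd = ai_sd, sex_effect = sex_effect,
                 age_effect = age_effect, site_sd = site_sd)
    if (!is.null(ov)) {
      if (is.null(names(ov)) && length(ov) == nrow(p)) names(ov) <- structures
      idx <- match(names(ov), p$structure)
      if (anyNA(idx)) stop("unknown structure in ", f, " override")
      p[[f]][idx] <- unname(ov)
    }
  }
  if (is.null(version_offsets)) {
    pv <- 1 - version_ref_frac
    delta <- sqrt(ref$sigma2_within * ref$eta2_version /
                    ((1 - ref$eta2_version) * pv * (1 - pv)))
    version_offsets <- lapply(seq_along(structures), function(i) {
      off <- c(0, rep(delta[i], length(version_labels) - 1L))
      names(off) <- version_labels
      off
    })
    names(version_offsets) <- structures
  }
  cfg <- structure(list(
    n_sites = as.integer(n_sites), n_range = as.integer(n_range),
    sex_ratio = sex_ratio, age_low_range = age_low_range,
    age_span_range = age_span_range, icv_mean = icv_mean, icv_sd = icv_sd,
    params = p, version_labels = version_labels,
    version_offsets = version_offsets, version_ref_frac = version_ref_frac,
    left_frac = left_frac, hand_known_frac = hand_known_frac,
    seed = as.integer(seed)), class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

#' Validate a simulator configuration
#'
#' @param cfg a `sim_config`.
#' @return `cfg`, invisibly; stops on the first violated invariant.
#' @export
validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with(cfg, {
    if (!is.finite(n_sites) || n_sites < 1) stop("n_sites must be >= 1")
    if (any(!is.finite(n_range)) || any(n_range < 2) || n_range[2] < n_range[1])
      stop("per-site n range must be >= 2 and ordered")
    if (!is.finite(sex_ratio) || sex_ratio <= 0 || sex_ratio >= 1)
      stop("sex_ratio must lie in (0, 1)")
    if (left_frac < 0 || left_frac > 1) stop("left_frac must lie in [0, 1]")
    if (any(!is.finite(unlist(params[-1])))) stop("non-finite structure parameter")
    if (any(abs(params$mean_ai) >= 1)) stop("mean AI must lie strictly inside (-1, 1)")
    off <- unlist(version_offsets)
    if (any(!is.finite(off)) || any(abs(off) >= 1))
      stop("version offsets must lie strictly inside (-1, 1)")
    if (any(params$ai_sd < 0) || any(params$site_sd < 0))
      stop("SDs must be non-negative")
    if (!is.finite(seed)) stop("seed must be a finite integer")
  })
  invisible(cfg)
}

#' Generate multi-site subject tables
#'
#' Draws one subject table per site under the generative model described in
#' [sim_config()]. Identical configuration and seed give bit-identical
#' output. For every subject, `compute_ai(L, R)` recovers the drawn AI to
#' machine precision because the total volume is split exactly.
#'
#' @param cfg a [sim_config()].
#' @return List of subject tables (data.frames in the [read_site_table()]
#'   schema), each carrying attributes `site_id`, `fs_version`, a
#'   per-structure `true_site_offset` vector and a `true_ai` matrix of the
#'   drawn asymmetry indices. The list itself carries a
#'   `sites` attribute (data.frame of per-site n, version, age window).
#' @export
generate_multisite <- function(cfg) {
  validate_sim_config(cfg)
  set.seed(cfg$seed)
  p <- cfg$params
  ns <- sample(seq(cfg$n_range[1], cfg$n_range[2]), cfg$n_sites, replace = TRUE)
  vref <- stats::runif(cfg$n_sites) < cfg$version_ref_frac
  versions <- ifelse(vref, cfg$version_labels[1],
                     sample(cfg$version_labels[-1], cfg$n_sites, replace = TRUE))
  age_lo <- stats::runif(cfg$n_sites, cfg$age_low_range[1], cfg$age_low_range[2])
  age_hi <- age_lo + stats::runif(cfg$n_sites, cfg$age_span_range[1],
                                  cfg$age_span_range[2])
  sdlog <- sqrt(log(1 + (cfg$icv_sd / cfg$icv_mean)^2))
  meanlog <- log(cfg$icv_mean) - sdlog^2 / 2

  out <- vector("list", cfg$n_sites)
  for (k in seq_len(cfg$n_sites)) {
    n <- ns[k]
    male <- stats::runif(n) < cfg$sex_ratio
    age <- stats::runif(n, age_lo[k], age_hi[k])
    icv <- stats::rlnorm(n, meanlog, sdlog)
    hand <- ifelse(stats::runif(n) < cfg$left_frac, "L", "R")
    hand[stats::runif(n) > cfg$hand_known_frac] <- NA_character_
    tab <- data.frame(
      subject_id = sprintf("s%02d_%04d", k, seq_len(n)),
      sex = ifelse(male, "M", "F"),
      age_years = age,
      handedness = hand,
      icv_mm3 = icv,
      stringsAsFactors = FALSE)
    site_off <- stats::rnorm(nrow(p), 0, p$site_sd)
    names(site_off) <- p$structure
    true_ai <- matrix(NA_real_, n, nrow(p), dimnames = list(NULL, p$structure))
    aic <- (age_lo[k] + age_hi[k]) / 2
    for (i in seq_len(nrow(p))) {
      s <- p$structure[i]
      voff <- cfg$version_offsets[[s]][[versions[k]]]
      ai <- p$mean_ai[i] + site_off[i] + voff +
        p$sex_effect[i] * (as.numeric(male) - 0.5) +
        p$age_effect[i] * (age - aic) +
        stats::rnorm(n, 0, p$ai_sd[i])
      ai <- pmax(pmin(ai, 0.999), -0.999)
      true_ai[, i] <- ai
      # total bilateral volume tied to head size (60 % of the ICV-scaled
      # mean), with 8 % residual spread
      tot <- p$mean_total[i] * (0.4 + 0.6 * icv / cfg$icv_mean) +
        stats::rnorm(n, 0, 0.08 * p$mean_total[i])
      tot <- pmax(tot, 1)
      tab[[paste0(s, "_L_mm3")]] <- tot * (1 + ai) / 2
      tab[[paste0(s, "_R_mm3")]] <- tot * (1 - ai) / 2
    }
    attr(tab, "site_id") <- sprintf("site%02d", k)
    attr(tab, "fs_version") <- versions[k]
    attr(tab, "true_site_offset") <- site_off
    attr(tab, "true_ai") <- true_ai
    out[[k]] <- tab
  }
  attr(out, "sites") <- data.frame(
    site_id = sprintf("site%02d", seq_len(cfg$n_sites)), n = ns,
    fs_version = versions, age_low = age_lo, age_high = age_hi,
    stringsAsFactors = FALSE)
  out
}
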