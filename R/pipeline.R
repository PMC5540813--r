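#' Run configuration for the two-level pipeline
#'
#' @param site_tables list of subject tables (in memory) or character vector
#'   of CSV paths.
#' @param pedigree,phenotypes optional pedigree data.frame / phenotype
#'   data.frame (or file paths) enabling the heritability stage.
#' @param structures structures to analyse (subset of the canonical seven).
#' @param contrasts which meta-analyses to run.
#' @param min_per_group,min_iqr_years meta-analysis inclusion filters
#'   (defaults 15 per group, 5-year age IQR).
#' @param alpha significance threshold used for fail-safe N (default 0.007,
#'   the Bonferroni level for seven structures as conventionally reported).
#' @param seed integer seed recorded in the manifest.
#' @param out_dir optional output directory; when given, all result tables,
#'   a JSON run manifest and an exclusion log are written there.
#' @return An object of class `run_config`.
#' @export
run_config <- function(site_tables, pedigree = NULL, phenotypes = NULL,
                       structures = ai_structures(),
                       contrasts = c("sex", "handedness", "age",
                                     "lateralization_male",
                                     "lateralization_female"),
                       min_per_group = 15, min_iqr_years = 5,
                       alpha = 0.007, seed = 1L, out_dir = NULL) {
  if (!all(structures %in% ai_structures()))
    stop("unknown structure(s): ",
         paste(setdiff(structures, ai_structures()), collapse = ", "))
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (is.character(site_tables) && !all(file.exists(site_tables)))
    stop("missing site table file(s): ",
         paste(site_tables[!file.exists(site_tables)], collapse = ", "))
  structure(list(site_tables = site_tables, pedigree = pedigree,
                 phenotypes = phenotypes, structures = structures,
                 contrasts = contrasts, min_per_group = min_per_group,
                 min_iqr_years = min_iqr_years, alpha = alpha,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

#' Run the full two-level analysis
#'
#' Executes the within-site stage independently per site — only summary
#' statistics cross the site boundary, mirroring a federated consortium in
#' which sites never share subject-level data — then pools the summaries by
#' random-effects meta-analysis per structure and contrast, partitions
#' between-dataset/between-version AI variance, and (when a pedigree and
#' phenotypes are supplied) fits the heritability models.
#'
#' @param config a [run_config()].
#' @return List with `summaries` (per site x structure), `meta` (per
#'   contrast), `age_regression`, `heterogeneity` (eta-squared table),
#'   `heritability` (NULL unless pedigree data given), `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  tabs <- config$site_tables
  if (is.character(tabs)) tabs <- lapply(tabs, read_site_table)

  summaries <- list(); ai_records <- list()
  for (i in seq_along(tabs)) {
    sid <- attr(tabs[[i]], "site_id") %||% sprintf("site%02d", i)
    sm <- tryCatch(
      site_summary(tabs[[i]], site_id = sid, structures = config$structures,
                   keep_ai = TRUE),
      error = function(e) stop("site stage failed for ", sid, ": ",
                               conditionMessage(e)))
    summaries[[i]] <- sm
    ai_records[[i]] <- attr(sm, "ai_records")
  }
  excl <- lapply(summaries, attr, "exclusions")
  names(excl) <- vapply(summaries, function(s) s$site_id[1], "")
  summaries <- do.call(rbind, summaries)
  ai_records <- do.call(rbind, ai_records)

  meta <- list()
  for (ct in config$contrasts) {
    meta[[ct]] <- tryCatch(
      meta_analyze(summaries, ct, structures = config$structures,
                   min_per_group = config$min_per_group,
                   min_iqr_years = config$min_iqr_years,
                   alpha = config$alpha),
      error = function(e) stop("meta stage failed for contrast ", ct, ": ",
                               conditionMessage(e)))
  }
  age_reg <- if ("age" %in% config$contrasts)
    age_meta_regression(summaries, config$structures,
                        config$min_per_group, config$min_iqr_years) else NULL
  het <- ai_heterogeneity(ai_records)

  herit <- NULL
  if (!is.null(config$pedigree)) {
    ped <- config$pedigree
    if (is.character(ped)) ped <- read_pedigree(ped)
    ph <- config$phenotypes
    if (is.character(ph)) ph <- utils::read.csv(ph, stringsAsFactors = FALSE)
    herit <- heritability_stage(ped, ph)
  }

  manifest <- list(
    package = "asymmeta",
    version = as.character(utils::packageVersion("asymmeta")),
    seed = config$seed, n_sites = length(tabs),
    structures = config$structures, contrasts = config$contrasts,
    min_per_group = config$min_per_group,
    min_iqr_years = config$min_iqr_years, alpha = config$alpha,
    exclusions = excl,
    config_hash = .config_hash(config))

  out <- list(summaries = summaries, meta = meta, age_regression = age_reg,
              heterogeneity = het, heritability = herit, manifest = manifest)
  if (!is.null(config$out_dir)) .write_results(out, config$out_dir)
  out
}

#' Heritability stage on a pedigree and phenotype table
#'
#' Fits the univariate polygenic model per phenotype column (covariates
#' age, sex, ICV) and, when left/right volume pairs or multiple asymmetry
#' indices are supplied, bivariate fits for genetic correlations.
#'
#' @param ped pedigree data.frame (see [read_pedigree()]).
#' @param phenotypes data.frame keyed by `individual_id`, with covariate
#'   columns `age`, `sex` (M/F), `icv` and one column per trait.
#' @param traits trait column names (default: every non-key, non-covariate
#'   column).
#' @param pairs if TRUE (default when >= 2 traits), also run pairwise
#'   bivariate fits.
#' @return List with `univariate` (data.frame: trait, h2, se, p, sigma2_g,
#'   sigma2_e) and `pairwise` (from [cross_ai_correlations()], or NULL).
#' @export
heritability_stage <- function(ped, phenotypes, traits = NULL, pairs = NULL) {
  idx <- match(phenotypes$individual_id, ped$individual_id)
  if (anyNA(idx)) stop("phenotype individual_id not found in pedigree")
  ped <- ped[idx, , drop = FALSE]   # align pedigree to phenotype rows
  K <- kinship_from_pedigree(ped)
  fam <- ped$family_id
  if (is.null(traits))
    traits <- setdiff(names(phenotypes),
                      c("individual_id", "age", "sex", "icv"))
  X <- cbind(age = phenotypes$age,
             sex = as.numeric(phenotypes$sex == "M"),
             icv = phenotypes$icv)
  uni <- lapply(traits, function(tr) {
    f <- fit_univariate_vc(phenotypes[[tr]], X, K, families = fam)
    data.frame(trait = tr, h2 = f$h2, se = f$h2_se, p = f$p,
               sigma2_g = f$sigma2_g, sigma2_e = f$sigma2_e,
               stringsAsFactors = FALSE)
  })
  uni <- do.call(rbind, uni)
  rownames(uni) <- NULL
  if (is.null(pairs)) pairs <- length(traits) >= 2L
  pw <- if (pairs && length(traits) >= 2L)
    cross_ai_correlations(as.matrix(phenotypes[traits]), X, K, families = fam)
  else NULL
  list(univariate = uni, pairwise = pw)
}

.config_hash <- function(config) {
  # order-stable fingerprint of the scalar settings; no external digest
  # dependency, so a simple serialization checksum is used
  s <- paste(utils::capture.output(utils::str(
    config[c("structures", "contrasts", "min_per_group", "min_iqr_years",
             "alpha", "seed")])), collapse = "\n")
  sprintf("%08x", sum(utf8ToInt(s) * seq_len(nchar(s))) %% .Machine$integer.max)
}

.write_results <- function(out, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_summary(out$summaries, file.path(dir, "dataset_summaries.csv"))
  for (ct in names(out$meta)) {
    write_summary(out$meta[[ct]], file.path(dir, paste0("meta_", ct, ".csv")))
    write_summary(attr(out$meta[[ct]], "per_site"),
                  file.path(dir, paste0("forest_", ct, ".csv")))
  }
  if (!is.null(out$age_regression))
    write_summary(out$age_regression, file.path(dir, "age_meta_regression.csv"))
  write_summary(out$heterogeneity, file.path(dir, "ai_heterogeneity.csv"))
  if (!is.null(out$heritability)) {
    write_summary(out$heritability$univariate, file.path(dir, "heritability.csv"))
    if (!is.null(out$heritability$pairwise))
      write_summary(out$heritability$pairwise,
                    file.path(dir, "genetic_correlations.csv"))
  }
  jsonlite::write_json(out$manifest, file.path(dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}
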