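#' Canonical subcortical structure names
#'
#' The seven bilaterally paired structures handled by the pipeline, in
#' canonical order: nucleus accumbens, amygdala, caudate nucleus, globus
#' pallidus, hippocampus, putamen, thalamus.
#'
#' @return Character vector of length 7.
#' @export
ai_structures <- function() {
  c("accumbens", "amygdala", "caudate", "pallidum",
    "hippocampus", "putamen", "thalamus")
}

#' Reference effect-size table for the seven subcortical asymmetry indices
#'
#' Consortium-scale estimates (15,847 subjects across 52 sites; family-based
#' heritabilities from 1170 individuals in 71 extended pedigrees) that the
#' synthetic-data generator uses as its default "true" world, and that the
#' consistency checks take as printed inputs.
#'
#' Columns:
#' \describe{
#'   \item{structure}{canonical structure name}
#'   \item{mean_ai}{population mean asymmetry index, \eqn{(L-R)/(L+R)}}
#'   \item{sigma2_within}{within-dataset AI variance}
#'   \item{eta2_dataset, eta2_version}{variance shares explained by dataset
#'     and by segmentation-software version (one-way eta squared)}
#'   \item{sex_effect}{pooled male-minus-female difference in residualised AI}
#'   \item{sex_k, sex_Q}{dataset count and Cochran's Q of the sex
#'     meta-analysis}
#'   \item{age_effect}{pooled per-year age coefficient on AI}
#'   \item{age_k}{dataset count of the age meta-analysis}
#'   \item{h2}{narrow-sense heritability of the AI}
#'   \item{rho_g, rho_e, rho_phen}{genetic, environmental and phenotypic
#'     correlations between left and right volumes}
#' }
#'
#' @return A data.frame with one row per structure.
#' @export
reference_effects <- function() {
  data.frame(
    structure     = ai_structures(),
    mean_ai       = c(-0.0072, -0.0205, -0.0095, 0.0180, -0.0066, 0.0194, 0.0211),
    sigma2_within = c(0.0061, 0.0027, 0.0006, 0.0027, 0.0008, 0.0008, 0.0009),
    eta2_dataset  = c(0.180, 0.103, 0.279, 0.171, 0.070, 0.065, 0.189),
    eta2_version  = c(0.130, 0.017, 0.014, 0.142, 0.010, 0.006, 0.333),
    sex_effect    = c(0.002, 5.7e-5, -1.3e-4, 0.004, 0.001, -0.002, -0.001),
    sex_k         = c(42L, 43L, 41L, 40L, 43L, 41L, 41L),
    sex_Q         = c(76.9, 33.37, 75.13, 52.49, 19.99, 24.49, 65.73),
    age_effect    = c(2.1e-6, -1.8e-4, 5.9e-5, -2.0e-4, -1.0e-4, 1.5e-4, 1.5e-4),
    age_k         = c(37L, 38L, 36L, 35L, 38L, 36L, 36L),
    h2            = c(0.114, 0.040, 0.096, 0.148, 0.180, 0.270, 0.228),
    rho_g         = c(0.841, 0.995, 0.974, 0.823, 0.939, 0.899, 0.824),
    rho_e         = c(0.34, 0.39, 0.56, 0.45, 0.53, 0.58, 0.56),
    rho_phen      = c(0.54, 0.71, 0.85, 0.57, 0.78, 0.78, 0.68),
    stringsAsFactors = FALSE
  )
}

# typical total (left+right) volumes in mm3; used by the generator to tie
# structure volumes to head size
.structure_volumes <- function() {
  c(accumbens = 1200, amygdala = 3100, caudate = 7600, pallidum = 3600,
    hippocampus = 8800, putamen = 10200, thalamus = 15800)
}
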