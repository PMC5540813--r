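#' Configuration for the extended-pedigree simulator
#'
#' Pedigrees follow a fixed three-generation template for reproducibility
#' and simple kinship verification: a founder couple has `n_children`
#' children, each child marries a new (unrelated) founder, and each couple
#' has `n_grandchildren` children. Defaults (71 pedigrees, 3 children, 3
#' grandchildren per couple: 17 individuals each, 1207 in total) emulate a
#' large family study of roughly 1170 subjects in 71 extended pedigrees.
#'
#' Traits follow the additive polygenic model: for trait t with total SD
#' `trait_sd[t]` and heritability `h2[t]`, genetic values are multivariate
#' normal with covariance \eqn{h^2 \sigma^2 \cdot 2\Phi} (2Phi the additive
#' relationship matrix), drawn through the Cholesky factor of each family's
#' 2Phi block; with two traits, genetic values share correlation `rho_g` and
#' environmental deviations share `rho_e`. Covariates age, sex and ICV are
#' attached with linear effects.
#'
#' @param n_pedigrees number of families (default 71).
#' @param n_children founder-couple children per family (default 3).
#' @param n_grandchildren children per married child (default 3).
#' @param h2 per-trait heritabilities in \[0, 1\] (length 1 or 2).
#' @param trait_sd per-trait total SDs (recycled to length of h2). Default
#'   0.028, the within-dataset SD of the putamen asymmetry index.
#' @param rho_g,rho_e genetic / environmental correlations (2-trait case).
#' @param beta_age,beta_sex,beta_icv covariate effects (per year; male minus
#'   female; per mm3).
#' @param age_range uniform age window, years.
#' @param icv_mean,icv_sd ICV scale, mm3.
#' @param seed integer seed (mandatory).
#' @return An object of class `pedigree_sim_config`.
#' @export
pedigree_sim_config <- function(n_pedigrees = 71, n_children = 3,
                                n_grandchildren = 3,
                                h2 = 0.27, trait_sd = 0.028,
                                rho_g = 0, rho_e = 0,
                                beta_age = 1.5e-4, beta_sex = -0.002,
                                beta_icv = 5e-9,
                                age_range = c(18, 85),
                                icv_mean = 1.5e6, icv_sd = 1.5e5,
                                seed) {
  if (missing(seed)) stop("seed is mandatory")
  n_traits <- length(h2)
  trait_sd <- rep_len(trait_sd, n_traits)
  cfg <- structure(list(
    n_pedigrees = as.integer(n_pedigrees), n_children = as.integer(n_children),
    n_grandchildren = as.integer(n_grandchildren),
    h2 = h2, trait_sd = trait_sd, rho_g = rho_g, rho_e = rho_e,
    beta_age = beta_age, beta_sex = beta_sex, beta_icv = beta_icv,
    age_range = age_range, icv_mean = icv_mean, icv_sd = icv_sd,
    seed = as.integer(seed)), class = "pedigree_sim_config")
  validate_pedigree_sim_config(cfg)
  cfg
}

#' Validate a pedigree simulator configuration
#'
#' Checks ranges and that the implied two-trait phenotypic covariance matrix
#' is positive semi-definite.
#'
#' @param cfg a `pedigree_sim_config`.
#' @return `cfg` invisibly; stops on violation.
#' @export
validate_pedigree_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "pedigree_sim_config"))
  with(cfg, {
    if (n_pedigrees < 1 || n_children < 1 || n_grandchildren < 0)
      stop("pedigree shape counts out of range")
    if (any(!is.finite(h2)) || any(h2 < 0) || any(h2 > 1))
      stop("h2 must lie in [0, 1]")
    if (length(h2) > 2) stop("at most 2 traits supported")
    if (abs(rho_g) > 1 || abs(rho_e) > 1)
      stop("correlations must lie in [-1, 1]")
    if (any(trait_sd < 0)) stop("trait_sd must be non-negative")
    if (length(h2) == 2) {
      P <- .gen_cov(h2, trait_sd, rho_g) + .env_cov(h2, trait_sd, rho_e)
      if (min(eigen(P, symmetric = TRUE, only.values = TRUE)$values) < -1e-12)
        stop("implied phenotypic covariance is not positive semi-definite")
    }
    if (!is.finite(seed)) stop("seed must be a finite integer")
  })
  invisible(cfg)
}

.gen_cov <- function(h2, sd, rho_g) {
  sg <- sqrt(h2) * sd
  R <- diag(length(h2)); R[R == 0] <- rho_g
  diag(sg, length(sg)) %*% R %*% diag(sg, length(sg))
}

.env_cov <- function(h2, sd, rho_e) {
  se <- sqrt(1 - h2) * sd
  R <- diag(length(h2)); R[R == 0] <- rho_e
  diag(se, length(se)) %*% R %*% diag(se, length(se))
}

# draw n x t matrix with vec-covariance Sigma_t (x) K  (K = 2*Phi block)
.draw_correlated <- function(K, Sigma) {
  n <- nrow(K); t <- nrow(Sigma)
  if (all(Sigma == 0)) return(matrix(0, n, t))
  ck <- chol(K + diag(1e-10, n))
  cs <- chol(Sigma + diag(1e-12, t))
  t(ck) %*% matrix(stats::rnorm(n * t), n, t) %*% cs
}

#' Generate extended pedigrees with bivariate polygenic phenotypes
#'
#' @param cfg a [pedigree_sim_config()].
#' @return List with `pedigree` (data.frame: family_id, individual_id,
#'   father_id, mother_id, sex; parent ids 0 for founders) and `phenotypes`
#'   (data.frame keyed by individual_id: trait1 \[, trait2\], age, sex, icv).
#'   Attribute `"truth"` stores the drawn genetic values.
#' @export
generate_pedigrees <- function(cfg) {
  validate_pedigree_sim_config(cfg)
  set.seed(cfg$seed)
  t <- length(cfg$h2)
  G <- .gen_cov(cfg$h2, cfg$trait_sd, cfg$rho_g)
  E <- .env_cov(cfg$h2, cfg$trait_sd, cfg$rho_e)

  peds <- vector("list", cfg$n_pedigrees)
  phen <- vector("list", cfg$n_pedigrees)
  gtruth <- vector("list", cfg$n_pedigrees)
  next_id <- 1L
  for (f in seq_len(cfg$n_pedigrees)) {
    ped <- .pedigree_template(f, cfg$n_children, cfg$n_grandchildren, next_id)
    next_id <- max(ped$individual_id) + 1L
    n <- nrow(ped)
    K <- kinship_from_pedigree(ped)
    g <- .draw_correlated(K, G)
    e <- matrix(stats::rnorm(n * t), n, t) %*% chol(E + diag(1e-12, t))
    age <- stats::runif(n, cfg$age_range[1], cfg$age_range[2])
    sexn <- as.numeric(ped$sex == 1)   # 1 = male
    sdlog <- sqrt(log(1 + (cfg$icv_sd / cfg$icv_mean)^2))
    icv <- stats::rlnorm(n, log(cfg$icv_mean) - sdlog^2 / 2, sdlog)
    fixed <- cfg$beta_age * age + cfg$beta_sex * (sexn - 0.5) +
      cfg$beta_icv * (icv - cfg$icv_mean)
    y <- g + e + matrix(fixed, n, t)
    ph <- data.frame(individual_id = ped$individual_id, y,
                     age = age, sex = ifelse(sexn == 1, "M", "F"), icv = icv,
                     stringsAsFactors = FALSE)
    names(ph)[2:(1 + t)] <- paste0("trait", seq_len(t))
    peds[[f]] <- ped; phen[[f]] <- ph; gtruth[[f]] <- g
  }
  out <- list(pedigree = do.call(rbind, peds),
              phenotypes = do.call(rbind, phen))
  rownames(out$pedigree) <- rownames(out$phenotypes) <- NULL
  attr(out, "truth") <- list(genetic_values = do.call(rbind, gtruth),
                             G = G, E = E)
  out
}

# founder couple -> n_children each married to a founder spouse ->
# n_grandchildren per couple; sexes alternate, spouse opposite
.pedigree_template <- function(family_id, n_children, n_grandchildren, start_id) {
  id <- function(k) start_id + k - 1L
  rows <- list(
    data.frame(family_id = family_id, individual_id = c(id(1), id(2)),
               father_id = 0L, mother_id = 0L, sex = c(1L, 2L)))
  k <- 3L
  for (c in seq_len(n_children)) {
    child_sex <- if (c %% 2 == 1) 1L else 2L
    child <- id(k); spouse <- id(k + 1L); k <- k + 2L
    rows[[length(rows) + 1L]] <- data.frame(
      family_id = family_id, individual_id = c(child, spouse),
      father_id = c(id(1), 0L), mother_id = c(id(2), 0L),
      sex = c(child_sex, 3L - child_sex))
    if (n_grandchildren > 0) {
      gids <- id(seq(k, k + n_grandchildren - 1L)); k <- k + n_grandchildren
      fa <- if (child_sex == 1L) child else spouse
      mo <- if (child_sex == 1L) spouse else child
      rows[[length(rows) + 1L]] <- data.frame(
        family_id = family_id, individual_id = gids,
        father_id = fa, mother_id = mo,
        sex = rep_len(c(1L, 2L), n_grandchildren))
    }
  }
  do.call(rbind, rows)
}

#' Additive relationship matrix from a pedigree
#'
#' Builds 2Phi (twice the kinship matrix) by the recursive tabular method:
#' founders have diagonal 1 and are mutually unrelated; for individual i
#' with parents f, m listed earlier, A\[i, j\] = (A\[f, j\] + A\[m, j\]) / 2
#' and A\[i, i\] = 1 + A\[f, m\] / 2. Individuals may be listed in any
#' order; an internal topological sort is applied. Under the non-inbred
#' template the diagonal is 1.
#'
#' @param ped data.frame with columns `individual_id`, `father_id`,
#'   `mother_id` (0 or NA for founders). Both parents must be present or
#'   both absent.
#' @return Symmetric matrix, dimnames = individual ids, rows/columns in the
#'   input order of `ped`.
#' @export
kinship_from_pedigree <- function(ped) {
  need <- c("individual_id", "father_id", "mother_id")
  if (!all(need %in% names(ped)))
    stop("pedigree must have columns ", paste(need, collapse = ", "))
  ids <- ped$individual_id
  if (anyDuplicated(ids)) stop("duplicate individual ids")
  fa <- ped$father_id; mo <- ped$mother_id
  fa[is.na(fa)] <- 0L; mo[is.na(mo)] <- 0L
  founder <- fa == 0 & mo == 0
  if (any(xor(fa == 0, mo == 0)))
    stop("individuals must have both parents present or both absent")
  fi <- match(fa, ids); mi <- match(mo, ids)
  if (any(!founder & (is.na(fi) | is.na(mi))))
    stop("parent id not found in pedigree")

  # topological order (parents first); failure to make progress = cycle
  n <- length(ids)
  placed <- founder
  ord <- which(founder)
  while (length(ord) < n) {
    ready <- !placed & placed[pmax(fi, 1L)] & placed[pmax(mi, 1L)]
    ready[is.na(ready)] <- FALSE
    if (!any(ready)) stop("pedigree contains a cycle")
    ord <- c(ord, which(ready))
    placed[ready] <- TRUE
  }

  A <- matrix(0, n, n, dimnames = list(ids, ids))
  diag(A)[founder] <- 1
  for (i in ord[!founder[ord]]) {
    prev <- ord[seq_len(match(i, ord) - 1L)]
    A[i, prev] <- (A[fi[i], prev] + A[mi[i], prev]) / 2
    A[prev, i] <- A[i, prev]
    A[i, i] <- 1 + A[fi[i], mi[i]] / 2
  }
  A
}
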