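# shared fixtures and independent oracles, built in code at test time

# dense multivariate-normal profile log-likelihood via Cholesky: the
# independent oracle for the eigendecomposition-based variance-component fit
dense_profile_loglik <- function(y, X, K, h2) {
  n <- length(y)
  if (!any(apply(X, 2, function(c) all(c == c[1])))) X <- cbind(1, X)
  V <- h2 * K + (1 - h2) * diag(n)
  ch <- chol(V)
  # GLS beta and profiled sigma2 under covariance sigma2 * V
  yt <- backsolve(ch, y, transpose = TRUE)
  Xt <- backsolve(ch, X, transpose = TRUE)
  beta <- qr.coef(qr(Xt), yt)
  r <- yt - Xt %*% beta
  sigma2 <- sum(r^2) / n
  -0.5 * (n * log(2 * pi * sigma2) + 2 * sum(log(diag(ch))) + n)
}

# brute-force fail-safe oracle: append mean-weight null studies one at a
# time until the fixed-effect pooled two-sided p is >= alpha
brute_failsafe <- function(y, se, alpha, max_m = 1e6) {
  w <- 1 / se^2
  wbar <- mean(w)
  m <- 0L
  repeat {
    z <- sum(w * y) / sqrt(sum(w) + m * wbar)
    if (2 * pnorm(-abs(z)) >= alpha) return(m)
    m <- m + 1L
    if (m > max_m) stop("brute-force fail-safe exceeded max_m")
  }
}

# a small hand-built subject table with known values
tiny_site_table <- function(n = 80, seed = 42, structure = "putamen",
                            mean_ai = 0.02, ai_sd = 0.03,
                            sex_effect = 0, age_effect = 0) {
  set.seed(seed)
  male <- rep(c(TRUE, FALSE), length.out = n)
  age <- runif(n, 20, 60)
  icv <- rnorm(n, 1.5e6, 1e5)
  ai <- mean_ai + sex_effect * (male - 0.5) + age_effect * (age - 40) +
    rnorm(n, 0, ai_sd)
  tot <- rnorm(n, 10000, 800)
  tab <- data.frame(subject_id = sprintf("t%03d", seq_len(n)),
                    sex = ifelse(male, "M", "F"),
                    age_years = age,
                    handedness = sample(c("L", "R"), n, TRUE, c(0.15, 0.85)),
                    icv_mm3 = icv, stringsAsFactors = FALSE)
  tab[[paste0(structure, "_L_mm3")]] <- tot * (1 + ai) / 2
  tab[[paste0(structure, "_R_mm3")]] <- tot * (1 - ai) / 2
  attr(tab, "site_id") <- "tiny"
  attr(tab, "fs_version") <- "5.3"
  attr(tab, "true_ai") <- ai
  tab
}

# parent-offspring row-index pairs (parent first) from a pedigree
po_pairs <- function(ped) {
  idx <- match(ped$individual_id, ped$individual_id)
  child <- which(ped$father_id != 0)
  fa <- match(ped$father_id[child], ped$individual_id)
  mo <- match(ped$mother_id[child], ped$individual_id)
  cbind(parent = c(fa, mo), child = c(child, child))
}

# grandparent-grandchild row-index pairs (grandparent first)
gp_pairs <- function(ped) {
  id2row <- function(ids) match(ids, ped$individual_id)
  rows <- list()
  for (i in which(ped$father_id != 0)) {
    for (p in id2row(c(ped$father_id[i], ped$mother_id[i]))) {
      if (ped$father_id[p] != 0) {
        gps <- id2row(c(ped$father_id[p], ped$mother_id[p]))
        rows[[length(rows) + 1L]] <- cbind(gps, i)
      }
    }
  }
  do.call(rbind, rows)
}

# pedigree with founders, full sibs, half sibs and grandchildren for
# kinship algebra checks (ids chosen so children precede parents nowhere)
algebra_pedigree <- function() {
  data.frame(
    family_id = 1L,
    individual_id = 1:8,
    father_id = c(0L, 0L, 1L, 1L, 0L, 1L, 0L, 3L),
    mother_id = c(0L, 0L, 2L, 2L, 0L, 5L, 0L, 7L),
    sex = c(1L, 2L, 1L, 2L, 2L, 1L, 2L, 1L))
  # 3,4: full sibs; 6: half sib of 3/4 (same father 1, mother 5);
  # 8: child of 3 and founder 7, so grandchild of 1/2
}
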