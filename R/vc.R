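#' @name variance_components
#' @title Pedigree variance-component models for asymmetry indices
#'
#' @description
#' The polygenic model assumes phenotypes are multivariate normal with
#' covariance \eqn{\sigma^2_g K + \sigma^2_e I}, where K = 2Phi is the
#' additive relationship matrix from [kinship_from_pedigree()]. Because K is
#' block-diagonal by family, each family block is eigendecomposed once;
#' rotating phenotypes and covariates onto the eigenbasis makes the
#' likelihood a product of independent univariate (or 2x2, for bivariate
#' fits) normals, so a fit costs one eigendecomposition plus a 1-D profile
#' optimisation over the heritability ratio. Fixed covariate effects are
#' profiled out by generalised least squares at every ratio, and the error
#' variance has a closed-form ML profile. Likelihood-ratio tests against the
#' boundary hypotheses h2 = 0 and rho_g = 1 use the 50:50
#' \eqn{\chi^2_0 : \chi^2_1} mixture.
NULL

# rotate phenotype/covariate rows onto the per-family eigenbasis of K
.vc_setup <- function(Y, X, K, families = NULL) {
  Y <- as.matrix(Y); X <- as.matrix(X)
  n <- nrow(Y)
  if (nrow(X) != n || nrow(K) != n) stop("dimension mismatch")
  if (!any(apply(X, 2, function(c) all(c == c[1]))))
    X <- cbind(`(intercept)` = 1, X)
  if (qr(X)$rank < ncol(X)) stop("covariate matrix is rank deficient")
  if (is.null(families)) families <- rep(1L, n)
  lambda <- numeric(n); Ys <- matrix(0, n, ncol(Y)); Xs <- matrix(0, n, ncol(X))
  colnames(Xs) <- colnames(X)
  for (idx in split(seq_len(n), families)) {
    eg <- eigen(K[idx, idx, drop = FALSE], symmetric = TRUE)
    if (min(eg$values) < -1e-8) stop("kinship matrix is not positive semi-definite")
    lambda[idx] <- pmax(eg$values, 0)
    Ys[idx, ] <- crossprod(eg$vectors, Y[idx, , drop = FALSE])
    Xs[idx, ] <- crossprod(eg$vectors, X[idx, , drop = FALSE])
  }
  list(lambda = lambda, Y = Ys, X = Xs, n = n)
}

# profile ML log-likelihood at a given heritability ratio; beta and the
# total variance are profiled out in closed form
.uni_profile <- function(su, h2) {
  d <- h2 * su$lambda + (1 - h2)
  if (any(d <= 0)) return(list(ll = -Inf))
  w <- 1 / d
  Xw <- su$X * w
  beta <- solve(crossprod(su$X, Xw), crossprod(Xw, su$Y[, 1]))
  r <- su$Y[, 1] - su$X %*% beta
  sigma2 <- sum(w * r^2) / su$n
  ll <- -0.5 * (su$n * log(2 * pi * sigma2) + sum(log(d)) + su$n)
  list(ll = ll, beta = drop(beta), sigma2 = sigma2)
}

#' Profile log-likelihood of the univariate polygenic model
#'
#' Diagnostic helper: the ML log-likelihood at a fixed heritability ratio,
#' with fixed effects and the total variance profiled out. Matches a dense
#' multivariate-normal evaluation with covariance
#' \eqn{\sigma^2 (h^2 K + (1-h^2) I)} at the profiled \eqn{\hat\beta},
#' \eqn{\hat\sigma^2}.
#'
#' @param y phenotype vector.
#' @param X covariate matrix (intercept added if absent).
#' @param K additive relationship matrix.
#' @param h2 heritability ratio in \[0, 1\].
#' @param families optional family labels enabling block-wise computation.
#' @return Log-likelihood value.
#' @export
vc_loglik <- function(y, X, K, h2, families = NULL) {
  su <- .vc_setup(cbind(y), X, K, families)
  .uni_profile(su, h2)$ll
}

#' Univariate polygenic heritability fit
#'
#' Maximum-likelihood variance-component estimation of the narrow-sense
#' heritability of a quantitative trait on a pedigree, with fixed covariate
#' effects (typically age, sex, ICV). See [variance_components] for the
#' model and algorithm; the significance of h2 is a likelihood-ratio test
#' against h2 = 0 with the 50:50 chi-squared boundary mixture.
#'
#' @param y phenotype vector.
#' @param X covariate matrix (intercept added if absent).
#' @param K additive relationship matrix (2Phi).
#' @param families optional family labels; block-diagonal K is then
#'   exploited for linear scaling in the number of families.
#' @return An object of class `vc_fit`: `h2`, `h2_se` (profile curvature),
#'   `p` (boundary LRT), `sigma2_g`, `sigma2_e`, `fixef`, `loglik`,
#'   `loglik0`, `n`, `boundary` flag.
#' @export
fit_univariate_vc <- function(y, X, K, families = NULL) {
  sdy <- stats::sd(y)
  if (!is.finite(sdy) || sdy == 0) stop("phenotype has zero variance")
  su <- .vc_setup(cbind(y / sdy), X, K, families)
  obj <- function(h2) .uni_profile(su, h2)$ll
  opt <- stats::optimize(obj, c(0, 1), maximum = TRUE, tol = 1e-8)
  cand <- rbind(c(opt$maximum, opt$objective), c(0, obj(0)), c(1, obj(1)))
  # prefer the smallest h2 among near-ties so an uninformative (flat)
  # likelihood resolves to the null boundary
  near <- cand[, 2] >= max(cand[, 2]) - 1e-7
  best <- cand[near, , drop = FALSE]
  best <- best[which.min(best[, 1]), ]
  h2 <- best[1]; ll <- best[2]
  at0 <- obj(0)
  lr <- max(0, 2 * (ll - at0))
  p <- 0.5 * stats::pchisq(lr, df = 1, lower.tail = FALSE)
  # SE from the curvature of the profile log-likelihood
  h <- 1e-4
  hs <- min(max(h2, h), 1 - h)
  d2 <- (obj(hs + h) - 2 * obj(hs) + obj(hs - h)) / h^2
  h2_se <- if (is.finite(d2) && d2 < 0) sqrt(-1 / d2) else NA_real_
  prof <- .uni_profile(su, h2)
  structure(list(
    h2 = h2, h2_se = h2_se, p = p,
    sigma2_g = h2 * prof$sigma2 * sdy^2,
    sigma2_e = (1 - h2) * prof$sigma2 * sdy^2,
    fixef = prof$beta * sdy, loglik = ll, loglik0 = at0, n = su$n,
    boundary = h2 %in% c(0, 1)), class = "vc_fit")
}

#' @export
print.vc_fit <- function(x, ...) {
  cat(sprintf("Polygenic fit (n = %d): h2 = %.3f (SE %.3f), p = %.3g%s\n",
              x$n, x$h2, x$h2_se, x$p,
              if (x$boundary) " [estimate at boundary]" else ""))
  invisible(x)
}

# 2x2 G and E from the working parameter vector
.biv_mats <- function(th, rho_g_fixed = NULL) {
  rho_g <- if (is.null(rho_g_fixed)) tanh(th[3]) else rho_g_fixed
  i <- if (is.null(rho_g_fixed)) 4L else 3L
  g1 <- exp(th[1]); g2 <- exp(th[2])
  e1 <- exp(th[i]); e2 <- exp(th[i + 1L]); rho_e <- tanh(th[i + 2L])
  list(G = matrix(c(g1, rho_g * sqrt(g1 * g2), rho_g * sqrt(g1 * g2), g2), 2),
       E = matrix(c(e1, rho_e * sqrt(e1 * e2), rho_e * sqrt(e1 * e2), e2), 2),
       rho_g = rho_g, rho_e = rho_e)
}

# negative log-likelihood of the bivariate model on the rotated data;
# per eigenvalue the 2x2 covariance is lambda*G + E, so everything is
# vectorised over individuals. Fixed effects are profiled by GLS.
.biv_negll <- function(th, su, rho_g_fixed = NULL) {
  m <- .biv_mats(th, rho_g_fixed)
  G <- m$G; E <- m$E
  s11 <- su$lambda * G[1, 1] + E[1, 1]
  s12 <- su$lambda * G[1, 2] + E[1, 2]
  s22 <- su$lambda * G[2, 2] + E[2, 2]
  det <- s11 * s22 - s12^2
  if (any(det <= 0) || any(s11 <= 0)) return(1e10)
  w11 <- s22 / det; w12 <- -s12 / det; w22 <- s11 / det
  X <- su$X; y1 <- su$Y[, 1]; y2 <- su$Y[, 2]
  A11 <- crossprod(X, X * w11); A12 <- crossprod(X, X * w12)
  A22 <- crossprod(X, X * w22)
  A <- rbind(cbind(A11, A12), cbind(A12, A22))
  b <- c(crossprod(X, w11 * y1 + w12 * y2), crossprod(X, w12 * y1 + w22 * y2))
  beta <- tryCatch(solve(A, b), error = function(e) NULL)
  if (is.null(beta)) return(1e10)
  p <- ncol(X)
  r1 <- y1 - X %*% beta[1:p]; r2 <- y2 - X %*% beta[(p + 1):(2 * p)]
  quad <- sum(w11 * r1^2 + 2 * w12 * r1 * r2 + w22 * r2^2)
  0.5 * (sum(log(det)) + quad + 2 * su$n * log(2 * pi))
}

#' Bivariate polygenic fit and genetic correlation
#'
#' Joint variance-component fit of two traits on one pedigree, covariance
#' \eqn{G \otimes K + E \otimes I} with 2x2 genetic and environmental
#' covariance matrices. Reports the genetic correlation
#' \eqn{\rho_g = G_{12}/\sqrt{G_{11} G_{22}}}, the environmental
#' correlation, and the model-implied phenotypic correlation
#' (from G + E, the per-individual total covariance for an outbred
#' individual). Likelihood-ratio tests are run against \eqn{\rho_g = 0}
#' (1 df) and against the boundary \eqn{\rho_g = 1} (50:50 chi-squared
#' mixture). The correlation is parameterised through tanh, so estimates are
#' always inside a positive-semi-definite cone.
#'
#' @param y1,y2 phenotype vectors over the same individuals.
#' @param X covariate matrix (intercept added if absent); shared by both
#'   traits.
#' @param K additive relationship matrix.
#' @param families optional family labels (block-wise computation).
#' @param fix_rho_g optionally fix the genetic correlation (used internally
#'   for the LRTs; exposed for profiling).
#' @param control passed to [stats::optim()] (Nelder-Mead).
#' @return An object of class `vc_fit_bi`: `rho_g`, `rho_g_se`, `p_rho0`,
#'   `p_rho1`, `rho_e`, `rho_phen`, `h2` (length 2), `G`, `E` (original
#'   trait scale), `loglik`, `n`.
#' @export
fit_bivariate_vc <- function(y1, y2, X, K, families = NULL,
                             fix_rho_g = NULL,
                             control = list(maxit = 2000, reltol = 1e-10)) {
  sd1 <- stats::sd(y1); sd2 <- stats::sd(y2)
  if (sd1 == 0 || sd2 == 0) stop("a phenotype has zero variance")
  su <- .vc_setup(cbind(y1 / sd1, y2 / sd2), X, K, families)

  # starting values: univariate fits for the variance splits, residual
  # correlation for both correlations
  f1 <- fit_univariate_vc(y1, X, K, families)
  f2 <- fit_univariate_vc(y2, X, K, families)
  h0 <- function(f) min(max(f$h2, 0.05), 0.95)
  r0 <- stats::cor(stats::lm.fit(su$X, su$Y[, 1])$residuals,
                   stats::lm.fit(su$X, su$Y[, 2])$residuals)
  r0 <- min(max(r0, -0.95), 0.95)
  th0 <- c(log(h0(f1)), log(h0(f2)),
           if (is.null(fix_rho_g)) atanh(r0),
           log(1 - h0(f1) + 1e-3), log(1 - h0(f2) + 1e-3), atanh(r0))

  fit <- stats::optim(th0, .biv_negll, su = su, rho_g_fixed = fix_rho_g,
                      method = "Nelder-Mead", control = control)
  m <- .biv_mats(fit$par, fix_rho_g)
  ll <- -fit$value

  rho_g_se <- p_rho0 <- p_rho1 <- NA_real_
  if (is.null(fix_rho_g)) {
    H <- tryCatch(stats::optimHess(fit$par, .biv_negll, su = su,
                                   rho_g_fixed = NULL),
                  error = function(e) NULL)
    if (!is.null(H)) {
      V <- tryCatch(solve(H), error = function(e) NULL)
      if (!is.null(V) && V[3, 3] > 0)
        rho_g_se <- sqrt(V[3, 3]) * (1 - m$rho_g^2)   # delta method on tanh
    }
    ll0 <- -stats::optim(th0[-3], .biv_negll, su = su, rho_g_fixed = 0,
                         method = "Nelder-Mead", control = control)$value
    ll1 <- -stats::optim(th0[-3], .biv_negll, su = su, rho_g_fixed = 1,
                         method = "Nelder-Mead", control = control)$value
    p_rho0 <- stats::pchisq(max(0, 2 * (ll - ll0)), 1, lower.tail = FALSE)
    lr1 <- max(0, 2 * (ll - ll1))
    p_rho1 <- 0.5 * stats::pchisq(lr1, 1, lower.tail = FALSE)
  }

  # back to the original trait scale
  S <- diag(c(sd1, sd2))
  G <- S %*% m$G %*% S; E <- S %*% m$E %*% S
  P <- G + E
  structure(list(
    rho_g = m$rho_g, rho_g_se = rho_g_se, p_rho0 = p_rho0, p_rho1 = p_rho1,
    rho_e = m$rho_e,
    rho_phen = P[1, 2] / sqrt(P[1, 1] * P[2, 2]),
    h2 = c(G[1, 1] / P[1, 1], G[2, 2] / P[2, 2]),
    G = G, E = E, loglik = ll, n = su$n,
    convergence = fit$convergence), class = "vc_fit_bi")
}

#' @export
print.vc_fit_bi <- function(x, ...) {
  cat(sprintf("Bivariate polygenic fit (n = %d)\n", x$n))
  cat(sprintf("  rho_g = %.3f (SE %.3f); p(rho=0) = %.3g, p(rho=1) = %.3g\n",
              x$rho_g, x$rho_g_se, x$p_rho0, x$p_rho1))
  cat(sprintf("  rho_e = %.3f; rho_phen = %.3f; h2 = (%.3f, %.3f)\n",
              x$rho_e, x$rho_phen, x$h2[1], x$h2[2]))
  invisible(x)
}

#' Pairwise phenotypic and genetic correlations across traits
#'
#' For every pair of traits (e.g. the seven asymmetry indices), reports the
#' phenotypic correlation of the covariate-residualised traits (with an
#' uncorrected correlation-test p-value) and the genetic correlation from a
#' bivariate variance-component fit (with its uncorrected LRT p against
#' rho_g = 0).
#'
#' @param traits numeric matrix, one column per trait (named).
#' @param X covariate matrix.
#' @param K additive relationship matrix.
#' @param families optional family labels.
#' @return data.frame with one row per unordered pair: `trait1`, `trait2`,
#'   `rho_phen`, `phen_p`, `rho_g`, `rho_g_se`, `p_rho0`.
#' @export
cross_ai_correlations <- function(traits, X, K, families = NULL) {
  traits <- as.matrix(traits)
  m <- ncol(traits)
  if (m < 2L) stop("need at least 2 traits")
  if (is.null(colnames(traits))) colnames(traits) <- paste0("trait", seq_len(m))
  res <- apply(traits, 2, function(y) residualize(y, X))
  rows <- list()
  for (i in seq_len(m - 1L)) for (j in seq((i + 1L), m)) {
    ct <- stats::cor.test(res[, i], res[, j])
    bf <- fit_bivariate_vc(traits[, i], traits[, j], X, K, families)
    rows[[length(rows) + 1L]] <- data.frame(
      trait1 = colnames(traits)[i], trait2 = colnames(traits)[j],
      rho_phen = unname(ct$estimate), phen_p = ct$p.value,
      rho_g = bf$rho_g, rho_g_se = bf$rho_g_se, p_rho0 = bf$p_rho0,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
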