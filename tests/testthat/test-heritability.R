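test_that("kinship coefficients match pedigree algebra", {
  K <- kinship_from_pedigree(algebra_pedigree())
  expect_equal(unname(diag(K)), rep(1, 8))        # non-inbred diagonal
  expect_equal(K["1", "3"], 0.5)                  # parent-offspring
  expect_equal(K["3", "4"], 0.5)                  # full siblings
  expect_equal(K["3", "6"], 0.25)                 # half siblings
  expect_equal(K["1", "8"], 0.25)                 # grandparent-grandchild
  expect_equal(K["4", "8"], 0.25)                 # avuncular
  expect_equal(K["1", "2"], 0)                    # unrelated founders
  expect_equal(K["5", "7"], 0)
  expect_true(isSymmetric(K))
})

test_that("kinship construction is order-independent and validates input", {
  ped <- algebra_pedigree()
  shuffled <- ped[c(8, 3, 1, 6, 2, 7, 4, 5), ]
  K1 <- kinship_from_pedigree(ped)
  K2 <- kinship_from_pedigree(shuffled)
  expect_equal(K2[rownames(K1), colnames(K1)], K1)
  bad <- ped; bad$mother_id[3] <- 0               # single missing parent
  expect_error(kinship_from_pedigree(bad), "both parents")
  cyc <- data.frame(family_id = 1, individual_id = 1:2,
                    father_id = c(2L, 1L), mother_id = c(2L, 1L), sex = 1:2)
  expect_error(kinship_from_pedigree(cyc), "cycle")
})

test_that("eigendecomposition likelihood equals the dense Cholesky oracle", {
  cfg <- pedigree_sim_config(n_pedigrees = 10, h2 = 0.4, seed = 61)
  sim <- generate_pedigrees(cfg)                   # n = 170 <= 200
  ped <- sim$pedigree; ph <- sim$phenotypes
  K <- kinship_from_pedigree(ped)
  X <- cbind(age = ph$age, sex = as.numeric(ph$sex == "M"), icv = ph$icv)
  sdy <- sd(ph$trait1); ys <- ph$trait1 / sdy      # oracle on the same scale
  for (h2 in c(0, 0.17, 0.5, 0.83, 1)) {
    expect_equal(vc_loglik(ys, X, K, h2, families = ped$family_id),
                 dense_profile_loglik(ys, X, K, h2),
                 tolerance = 1e-6, info = paste("h2 =", h2))
  }
})

test_that("univariate fit is profile-optimal and recovers strong signal", {
  cfg <- pedigree_sim_config(n_pedigrees = 40, h2 = 0.6, seed = 62)
  sim <- generate_pedigrees(cfg)
  ped <- sim$pedigree; ph <- sim$phenotypes
  K <- kinship_from_pedigree(ped)
  X <- cbind(age = ph$age, sex = as.numeric(ph$sex == "M"), icv = ph$icv)
  f <- fit_univariate_vc(ph$trait1, X, K, families = ped$family_id)
  # optimum beats both boundaries
  expect_gte(f$loglik, f$loglik0)
  expect_gte(f$loglik, vc_loglik(ph$trait1 / sd(ph$trait1), X, K, 1,
                                 families = ped$family_id))
  expect_lt(abs(f$h2 - 0.6), 3 * f$h2_se)
  expect_lt(f$p, 0.007)
  # age covariate effect recovered within sampling error (abs bound ~4 SE)
  expect_lt(abs(unname(f$fixef["age"]) - cfg$beta_age), 3e-4)
})

test_that("unrelated-individuals data drives h2 to the zero boundary", {
  set.seed(63)
  n <- 300
  K <- diag(n)                                     # no family structure
  X <- cbind(age = runif(n, 20, 70))
  y <- rnorm(n)
  f <- fit_univariate_vc(y, X, K)
  expect_lt(f$h2, 0.15)
  expect_gt(f$p, 0.007)
  # boundary mixture: p is capped at 0.5 and attained when LR = 0
  expect_lte(f$p, 0.5)
  if (f$h2 == 0) expect_equal(f$p, 0.5)
})

test_that("noiseless genetic trait fits at the h2 = 1 boundary", {
  cfg <- pedigree_sim_config(n_pedigrees = 20, h2 = 1, trait_sd = 1,
                             beta_age = 0, beta_sex = 0, beta_icv = 0,
                             seed = 64)
  sim <- generate_pedigrees(cfg)
  ped <- sim$pedigree
  K <- kinship_from_pedigree(ped)
  X <- matrix(1, nrow(ped), 1)
  f <- fit_univariate_vc(sim$phenotypes$trait1, X, K,
                         families = ped$family_id)
  expect_gt(f$h2, 0.95)
  expect_true(f$boundary || f$h2 > 0.98)
})

test_that("bivariate fit identifies complete and absent pleiotropy", {
  # identical genetic values: rho_g ~ 1 and rho_g = 1 not rejected
  cfg1 <- pedigree_sim_config(n_pedigrees = 40, h2 = c(0.6, 0.6),
                              rho_g = 1, rho_e = 0.2, seed = 65)
  sim <- generate_pedigrees(cfg1)
  ped <- sim$pedigree; ph <- sim$phenotypes
  K <- kinship_from_pedigree(ped)
  X <- cbind(age = ph$age, sex = as.numeric(ph$sex == "M"), icv = ph$icv)
  fb <- fit_bivariate_vc(ph$trait1, ph$trait2, X, K, families = ped$family_id)
  expect_gt(fb$rho_g, 0.9)
  expect_gt(fb$p_rho1, 0.007)
  expect_lt(fb$p_rho0, 0.007)
  # independent genetic effects: rho_g scatters around 0 and the rho_g = 0
  # test stays calibrated (a single draw can reject by chance, so check
  # across replicates)
  fits0 <- lapply(1:5, function(i) {
    cfg0 <- pedigree_sim_config(n_pedigrees = 40, h2 = c(0.6, 0.6),
                                rho_g = 0, rho_e = 0.2, seed = 660 + i)
    sim0 <- generate_pedigrees(cfg0)
    ped0 <- sim0$pedigree; ph0 <- sim0$phenotypes
    K0 <- kinship_from_pedigree(ped0)
    X0 <- cbind(age = ph0$age, sex = as.numeric(ph0$sex == "M"), icv = ph0$icv)
    fit_bivariate_vc(ph0$trait1, ph0$trait2, X0, K0,
                     families = ped0$family_id)
  })
  expect_lt(abs(median(sapply(fits0, `[[`, "rho_g"))), 0.2)
  expect_lte(sum(sapply(fits0, `[[`, "p_rho0") < 0.007), 1L)
})

test_that("model-implied phenotypic correlation matches the empirical one", {
  cfg <- pedigree_sim_config(n_pedigrees = 60, h2 = c(0.5, 0.5),
                             rho_g = 0.8, rho_e = 0.3, seed = 67)
  sim <- generate_pedigrees(cfg)
  ped <- sim$pedigree; ph <- sim$phenotypes
  K <- kinship_from_pedigree(ped)
  X <- cbind(age = ph$age, sex = as.numeric(ph$sex == "M"), icv = ph$icv)
  fb <- fit_bivariate_vc(ph$trait1, ph$trait2, X, K, families = ped$family_id)
  emp <- cor(residualize(ph$trait1, X), residualize(ph$trait2, X))
  expect_lt(abs(fb$rho_phen - emp), 0.05)
  # truth: h2*rho_g + (1-h2)*rho_e = 0.55
  expect_lt(abs(fb$rho_phen - 0.55), 0.1)
})

test_that("a phenotypically null pair with compensating rho_g and rho_e is resolved", {
  # h2 = 0.5 each, rho_g = 0.6, rho_e = -0.6 implies rho_phen = 0
  cfg <- pedigree_sim_config(n_pedigrees = 71, h2 = c(0.5, 0.5),
                             rho_g = 0.6, rho_e = -0.6, seed = 68)
  sim <- generate_pedigrees(cfg)
  ped <- sim$pedigree; ph <- sim$phenotypes
  K <- kinship_from_pedigree(ped)
  X <- cbind(age = ph$age, sex = as.numeric(ph$sex == "M"), icv = ph$icv)
  fb <- fit_bivariate_vc(ph$trait1, ph$trait2, X, K, families = ped$family_id)
  expect_lt(abs(fb$rho_phen), 0.12)
  expect_gt(fb$rho_g, 0.25)
  expect_lt(fb$rho_e, -0.25)
})

test_that("cross-trait correlation table covers all pairs with sane values", {
  cfg <- pedigree_sim_config(n_pedigrees = 30, h2 = c(0.5, 0.5),
                             rho_g = -0.5, rho_e = -0.2, seed = 69)
  sim <- generate_pedigrees(cfg)
  ped <- sim$pedigree; ph <- sim$phenotypes
  K <- kinship_from_pedigree(ped)
  X <- cbind(age = ph$age, sex = as.numeric(ph$sex == "M"), icv = ph$icv)
  tab <- cross_ai_correlations(cbind(a = ph$trait1, b = ph$trait2), X, K,
                               families = ped$family_id)
  expect_equal(nrow(tab), 1L)
  expect_lt(tab$rho_g, 0)
  expect_lt(tab$rho_phen, 0)
  expect_true(all(abs(c(tab$rho_g, tab$rho_phen)) <= 1))
})
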