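test_that("compute_ai matches hand arithmetic and handles boundaries", {
  expect_equal(compute_ai(110, 90), 0.1)
  expect_equal(compute_ai(100, 100), 0)
  expect_equal(compute_ai(0, 50), -1)
  expect_equal(compute_ai(50, 0), 1)
  # antisymmetry over random volumes
  set.seed(1)
  L <- runif(200, 10, 1000); R <- runif(200, 10, 1000)
  expect_equal(compute_ai(L, R), -compute_ai(R, L))
  expect_true(all(abs(compute_ai(L, R)) <= 1))
  # missing sides propagate NA, errors on invalid input
  expect_true(is.na(compute_ai(NA, 50)))
  expect_error(compute_ai(0, 0), "positive")
  expect_error(compute_ai(-1, 5), "non-negative")
})

test_that("adaptive SD threshold follows the three sample-size bands", {
  expect_equal(sd_threshold(100), 2.5)
  expect_equal(sd_threshold(149), 2.5)
  expect_equal(sd_threshold(150), 3.0)
  expect_equal(sd_threshold(500), 3.0)
  expect_equal(sd_threshold(1000), 3.0)
  expect_equal(sd_threshold(1001), 3.5)
  expect_equal(sd_threshold(1500), 3.5)
  expect_error(sd_threshold(0), ">= 1")
})

test_that("outlier mask equals the brute-force z-score mask", {
  # the spec's worked vector: oracle decides whether 100 is flagged
  v <- c(0, 0, 0, 0, 100)
  brute <- abs(v - mean(v)) <= 2.5 * sd(v)
  expect_equal(exclude_outliers(v, 2.5), brute)
  # random vectors across thresholds
  set.seed(7)
  for (thr in c(2.5, 3, 3.5)) {
    x <- rnorm(500)
    expect_equal(exclude_outliers(x, thr), abs(x - mean(x)) <= thr * sd(x))
  }
  # degenerate cases
  expect_true(all(exclude_outliers(rep(5, 10), 2.5)))
  expect_error(exclude_outliers(c(1, NA), 2.5), "finite")
})

test_that("outlier exclusion rate matches the normal tail probability", {
  set.seed(11)
  x <- rnorm(1e5)
  frac <- mean(!exclude_outliers(x, 3.5))
  p <- 2 * pnorm(-3.5)                   # 4.65e-4
  expect_lt(abs(frac - p), 4 * sqrt(p * (1 - p) / 1e5))
})

test_that("residualization satisfies the OLS normal equations", {
  set.seed(2)
  n <- 300
  X <- cbind(age = runif(n, 20, 70), icv = rnorm(n, 1.5e6, 1e5))
  y <- rnorm(n)
  r <- residualize(y, X)
  expect_equal(mean(r), 0, tolerance = 1e-12)
  expect_lt(abs(sum(r * scale(X[, 1]))), 1e-8 * n)
  expect_lt(abs(sum(r * scale(X[, 2]))), 1e-8 * n)
  # covariate orthogonal to y (constructed): residuals = y - mean(y)
  x_orth <- residualize(rnorm(n), cbind(y))  # orthogonalize x against y
  y2 <- y - mean(y)
  r2 <- residualize(y, cbind(x = x_orth))
  expect_equal(r2, y2 - sum(y2 * x_orth) / sum(x_orth^2) * x_orth,
               tolerance = 1e-10)
  # exact linear signal: residuals vanish
  expect_equal(residualize(3 + 2 * X[, 1], X), rep(0, n), tolerance = 1e-8)
  # rank deficiency names the collinear column
  expect_error(residualize(y, cbind(a = X[, 1], b = 2 * X[, 1])),
               "collinear.*b")
})

test_that("Welch test reproduces hand-computed Satterthwaite values", {
  w <- welch_test(c(1, 2, 3), c(2, 3, 4))
  expect_equal(w$mean_diff, -1)
  expect_equal(w$se, sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(w$t, -1 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(w$df, 4, tolerance = 1e-12)
  # identical groups: t = 0, p = 1
  w0 <- welch_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(w0$t, 0)
  expect_equal(w0$p, 1)
  # balanced equal-variance case equals the pooled-variance Student t
  set.seed(3)
  a <- rnorm(40); b <- rnorm(40) + 0.3
  sp2 <- (var(a) + var(b)) / 2
  t_pooled <- (mean(a) - mean(b)) / sqrt(sp2 * 2 / 40)
  expect_equal(welch_test(a, b)$t, t_pooled, tolerance = 1e-12)
  expect_error(welch_test(rep(1, 5), rep(2, 5)), "degenerate")
})

test_that("ANCOVA age coefficient behaves over exact and simulated signal", {
  set.seed(4)
  n <- 400
  age <- runif(n, 20, 70); sex <- rbinom(n, 1, 0.5); icv <- rnorm(n, 1.5e6, 1e5)
  # constant AI: zero coefficient ("perfect fit" warnings are expected here)
  a0 <- suppressWarnings(ancova_age(rep(0.02, n), age, sex, icv))
  expect_equal(a0$age_coef, 0, tolerance = 1e-12)
  # exact linear signal recovered exactly
  a1 <- suppressWarnings(ancova_age(0.001 * age, age, sex, icv))
  expect_equal(a1$age_coef, 0.001, tolerance = 1e-10)
  expect_error(ancova_age(rnorm(n), rep(30, n), sex, icv), "constant")
  # simulated per-year effect at the consortium putamen magnitude
  set.seed(5)
  n <- 1e4
  age <- runif(n, 10, 80); sex <- rbinom(n, 1, 0.5); icv <- rnorm(n, 1.5e6, 1e5)
  ai <- 0.02 + 1.5e-4 * age + rnorm(n, 0, 0.028)
  a2 <- ancova_age(ai, age, sex, icv)
  expect_lt(abs(a2$age_coef - 1.5e-4), 3 * a2$se)
})

test_that("one-sample lateralization test has the right sign and power", {
  expect_equal(one_sample_lateralization(c(-1, 1, -0.5, 0.5))$t, 0)
  set.seed(10)
  expect_gt(one_sample_lateralization(rep(0.1, 50) + rnorm(50, 0, 1e-4))$t, 100)
  expect_error(one_sample_lateralization(rep(0.3, 10)), "zero variance")
  # power at alpha = 0.007 vs the noncentral-t closed form
  n <- 100; mu <- 0.02; s <- 0.03; alpha <- 0.007
  ncp <- mu / (s / sqrt(n))
  tc <- qt(1 - alpha / 2, n - 1)
  power <- pt(-tc, n - 1, ncp) + pt(tc, n - 1, ncp, lower.tail = FALSE)
  set.seed(6)
  rej <- mean(replicate(2000, {
    one_sample_lateralization(rnorm(n, mu, s))$p < alpha
  }))
  expect_lt(abs(rej - power), 4 * sqrt(power * (1 - power) / 2000))
})

test_that("SE reconstruction inverts the t-based confidence interval", {
  expect_equal(se_from_ci(-0.1, 0.3, 1e6), 0.4 / (2 * 1.959964),
               tolerance = 1e-4)
  expect_equal(se_from_ci(0, 0.2, 4), 0.2 / (2 * 2.776445), tolerance = 1e-5)
  # round-trips a Welch CI to its own SE
  set.seed(8)
  w <- welch_test(rnorm(30), rnorm(25, 0.5))
  expect_equal(se_from_ci(w$ci[1], w$ci[2], w$df), w$se, tolerance = 1e-12)
  expect_error(se_from_ci(0, 1, 0.5), "df")
  expect_error(se_from_ci(1, 0, 10), "upper")
})

test_that("residualized Welch p-values are uniform under the null", {
  # zero-effect synthetic sites: KS test on 1000 replicate p-values
  set.seed(9)
  ps <- replicate(1000, {
    n <- 60
    male <- rep(c(TRUE, FALSE), n / 2)
    age <- runif(n, 20, 60); icv <- rnorm(n, 1.5e6, 1e5)
    ai <- rnorm(n, 0, 0.03)
    r <- residualize(ai, cbind(age, icv))
    welch_test(r[male], r[!male])$p
  })
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("site summary is deterministic and respects its inputs", {
  tab <- tiny_site_table(n = 120, seed = 13, sex_effect = -0.01)
  s1 <- site_summary(tab, structures = "putamen")
  s2 <- site_summary(tab, structures = "putamen")
  expect_identical(s1, s2)   # idempotent re-run
  expect_equal(s1$structure, "putamen")
  expect_lte(s1$n, nrow(tab))
  expect_equal(s1$n_male + s1$n_female, s1$n)
  expect_gt(s1$sex_se, 0)
  # male-minus-female sign convention
  expect_lt(s1$sex_diff, 0)
  # the drawn negative sex effect should be roughly recovered
  expect_lt(abs(s1$sex_diff - (-0.01)), 4 * s1$sex_se)
})
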