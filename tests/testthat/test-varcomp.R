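test_that("identity kinship collapses to OLS with a degeneracy flag", {
  set.seed(1)
  n <- 200
  X <- cbind(age = rnorm(n, 50, 10))
  y <- 0.02 * X[, 1] + rnorm(n)
  fit <- reml_fit(y, X, kinship = diag(0.5, n))
  expect_true("kinship_identity_unidentifiable" %in% fit$flags)
  ols <- lm(y ~ X)
  s2_ols <- sum(residuals(ols)^2) / (n - 2)
  expect_equal(unname(fit$varcomp[["genetic"]] + fit$varcomp[["residual"]]),
               s2_ols, tolerance = 1e-4)
})

test_that("an identity household design is detected as unidentifiable", {
  ph <- simulate_phenotype(fix_ped, fix_K, cfg = sim_config(0.3, 0, seed = 2))
  fit <- reml_fit(ph$y, NULL, fix_K,
                  household = as.character(seq_len(nrow(fix_ped))),
                  eigen_A = fix_eigen)
  expect_true("household_identity_unidentifiable" %in% fit$flags)
  expect_equal(unname(fit$varcomp[["household"]]), 0)
})

test_that("restricted likelihood at the optimum beats random starts", {
  ph <- simulate_phenotype(fix_ped, fix_K,
                           cfg = sim_config(0.35, 0.08, seed = 3))
  X <- mqtlkit:::covariate_matrix(ph, c("age", "sex"))
  fit <- reml_fit(ph$y, X, fix_K, household = ph$household,
                  eigen_A = fix_eigen)
  yt <- crossprod(fix_eigen$U, ph$y)
  Xf <- cbind(1, X)
  Xt <- crossprod(fix_eigen$U, Xf)
  Z <- mqtlkit:::household_design(fix_ped)
  Zt <- crossprod(fix_eigen$U, Z)
  set.seed(4)
  for (i in 1:20) {
    h2 <- runif(1, 0.01, 0.9); c2 <- runif(1, 0.01, 0.9 - h2)
    e2 <- 1 - h2 - c2
    ev <- mqtlkit:::reml_eval(h2 / e2, c2 / e2, fix_eigen$d,
                              as.vector(yt), Xt, Zt)
    expect_gte(fit$logLik, ev$ll - 1e-6)
  }
})

test_that("estimates are invariant to permuting individuals", {
  ph <- simulate_phenotype(fix_ped, fix_K,
                           cfg = sim_config(0.4, 0.06, seed = 5))
  X <- mqtlkit:::covariate_matrix(ph, c("age", "sex"))
  fit1 <- reml_fit(ph$y, X, fix_K, household = ph$household,
                   eigen_A = fix_eigen)
  set.seed(6)
  pp <- sample(nrow(fix_ped))
  fit2 <- reml_fit(ph$y[pp], X[pp, ], fix_K[pp, pp],
                   household = ph$household[pp])
  expect_equal(fit1$h2, fit2$h2, tolerance = 1e-4)
  expect_equal(fit1$c2, fit2$c2, tolerance = 1e-4)
  expect_equal(fit1$logLik, fit2$logLik, tolerance = 1e-4)
})

test_that("heritability ratios follow the variance components", {
  v <- structure(list(varcomp = c(genetic = 4, household = 1, residual = 5),
                      converged = TRUE), class = "reml_fit")
  expect_equal(unname(heritability(v)), c(0.4, 0.1))
  v2 <- structure(list(varcomp = c(genetic = 2, household = 0, residual = 2),
                       converged = TRUE), class = "reml_fit")
  expect_equal(unname(heritability(v2))[1], 0.5)
  v0 <- structure(list(varcomp = c(genetic = 0, household = 0, residual = 0),
                       converged = TRUE), class = "reml_fit")
  expect_error(heritability(v0), class = "mqtl_undefined_ratio")
})

test_that("a null-heritability trait is fit at or near the zero boundary", {
  near0 <- vapply(1:5, function(s) {
    ph <- simulate_phenotype(fix_ped, fix_K,
                             cfg = sim_config(0, 0, seed = 60 + s))
    reml_fit(ph$y, NULL, fix_K, eigen_A = fix_eigen)$h2
  }, numeric(1))
  expect_gte(sum(near0 < 0.08), 4)
})

test_that("moderate-n recovery is unbiased enough to be useful", {
  est <- vapply(1:3, function(s) {
    ph <- simulate_phenotype(fix_ped, fix_K,
                             cfg = sim_config(0.5, 0.1, seed = 70 + s))
    fit <- fit_polygenic(ph, "y", c("age", "sex"), fix_K)
    c(fit$h2, fit$c2)
  }, numeric(2))
  expect_lt(abs(mean(est[1, ]) - 0.5), 0.15)
  expect_lt(abs(mean(est[2, ]) - 0.1), 0.08)
})

test_that("tidy and glance expose the fit in broom shape", {
  ph <- simulate_phenotype(fix_ped, fix_K, cfg = sim_config(0.3, 0.05,
                                                            seed = 8))
  fit <- fit_polygenic(ph, "y", c("age", "sex"), fix_K)
  td <- tidy(fit)
  expect_named(td, c("term", "estimate", "std.error"))
  expect_equal(td$term[4:5], c("h2", "c2"))
  expect_true(all(td$estimate[1:3] >= 0))
  gl <- glance(fit)
  expect_named(gl, c("logLik", "converged", "n", "p", "flags"))
  expect_true(gl$converged)
  # SEs exist for estimable components
  expect_true(is.finite(td$std.error[td$term == "h2"]))
})

test_that("rank-deficient covariates and misaligned kinship error out", {
  y <- rnorm(50)
  expect_error(reml_fit(y, cbind(1, 1:50, 1:50), diag(0.5, 50)),
               class = "mqtl_invalid_argument")
  expect_error(reml_fit(y, NULL, diag(0.5, 49)),
               class = "mqtl_invalid_argument")
})
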