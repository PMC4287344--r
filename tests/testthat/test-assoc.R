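test_that("null model under identity kinship reduces to OLS", {
  set.seed(1)
  n <- 300
  X <- cbind(age = rnorm(n, 50, 10), sex = rbinom(n, 1, 0.5))
  y <- 0.01 * X[, 1] + rnorm(n)
  nf <- null_model(y, X, diag(0.5, n))
  ols <- lm.fit(cbind(1, X), y)
  expect_equal(nf$resid, unname(ols$residuals), tolerance = 1e-6)
  # GLS normal equations hold in general
  expect_lt(max(abs(crossprod(nf$X, nf$Vi_r))), 1e-6)
  expect_error(null_model(y[1:10], X[1:10, ], diag(0.5, n)),
               class = "mqtl_invalid_argument")
})

test_that("score test equals the classical OLS score test at K = I", {
  set.seed(2)
  n <- 300
  X <- cbind(age = rnorm(n, 50, 10), sex = rbinom(n, 1, 0.5))
  y <- 0.01 * X[, 1] + rnorm(n)
  nf <- null_model(y, X, diag(0.5, n))
  for (i in 1:50) {
    g <- rbinom(n, 2, runif(1, 0.1, 0.5))
    p_mm <- score_test(nf, g)$p
    p_ols <- ols_score_test(y, X, g)
    expect_equal(p_mm, p_ols, tolerance = 1e-6)
  }
})

test_that("vectorized GWAS equals the per-variant score test", {
  ph <- simulate_phenotype(fix_ped, fix_K, cfg = sim_config(0.4, 0, seed = 3))
  X <- mqtlkit:::covariate_matrix(ph, c("age", "sex"))
  nf <- null_model(ph$y, X, fix_K, eigen_A = fix_eigen)
  G <- simulate_genotypes(fix_ped, variant_spec(runif(20, 0.1, 0.5)),
                          seed = 4)
  scan <- run_gwas(nf, G)
  single <- purrr::map_dbl(1:20, function(j)
    score_test(nf, G$dosage[, j])$p)
  expect_equal(scan$p, single, tolerance = 1e-10)
  betas <- purrr::map_dbl(1:20, function(j)
    score_test(nf, G$dosage[, j])$beta)
  expect_equal(scan$beta, betas, tolerance = 1e-10)
})

test_that("p-values are invariant under affine trait rescaling", {
  ph <- simulate_phenotype(fix_ped, fix_K, cfg = sim_config(0.4, 0, seed = 5))
  G <- simulate_genotypes(fix_ped, variant_spec(c(0.2, 0.4)), seed = 6)
  nf1 <- null_model(ph$y, NULL, fix_K, eigen_A = fix_eigen)
  nf2 <- null_model(3.7 * ph$y - 11, NULL, fix_K, eigen_A = fix_eigen)
  for (j in 1:2) {
    expect_equal(score_test(nf1, G$dosage[, j])$p,
                 score_test(nf2, G$dosage[, j])$p, tolerance = 1e-6)
  }
})

test_that("genotype codings and degenerate variants behave as defined", {
  ph <- simulate_phenotype(fix_ped, fix_K, cfg = sim_config(0, 0, seed = 7))
  nf <- null_model(ph$y, NULL, fix_K, eigen_A = fix_eigen)
  expect_equal(mqtlkit:::code_genotype(c(0, 1, 2, 1), "overdominant"),
               c(0, 1, 0, 1))
  expect_equal(mqtlkit:::code_genotype(c(0, 1, 2), "dominant"), c(0, 1, 1))
  expect_equal(mqtlkit:::code_genotype(c(0, 1, 2), "recessive"), c(0, 0, 1))
  mono <- rep(0, nrow(fix_ped))
  res <- score_test(nf, mono)
  expect_true(is.na(res$p))
  expect_match(res$note, "monomorphic")
  # rare variant: recessive coding collapses, skipped with reason
  g <- c(1, rep(0, nrow(fix_ped) - 1))
  sc <- genotype_model_scan(nf, g)
  expect_true(is.na(sc$p[sc$model == "recessive"]))
  expect_true(any(sc$best))
})

test_that("additive dosage test matches the hard-call additive branch", {
  ph <- simulate_phenotype(fix_ped, fix_K, cfg = sim_config(0.3, 0, seed = 8))
  nf <- null_model(ph$y, NULL, fix_K, eigen_A = fix_eigen)
  G <- simulate_genotypes(fix_ped, variant_spec(0.3), seed = 9)
  g <- G$dosage[, 1]  # integral dosages
  p_add <- score_test(nf, g)$p
  sc <- genotype_model_scan(nf, g)
  expect_equal(sc$p[sc$model == "additive"], p_add, tolerance = 1e-12)
})

test_that("explained variance matches the correlation oracle", {
  ph <- simulate_phenotype(fix_ped, fix_K, cfg = sim_config(0, 0, seed = 10))
  G <- simulate_genotypes(fix_ped, variant_spec(0.3), seed = 11)
  g <- G$dosage[, 1]
  y <- ph$y + 0.5 * (g - mean(g))
  X <- mqtlkit:::covariate_matrix(ph, c("age", "sex"))
  nf <- null_model(y, X, fix_K, eigen_A = fix_eigen)
  st <- score_test(nf, g)
  r2 <- explained_variance(nf, g, "additive", st$beta)
  oracle <- 100 * cor(g, nf$resid)^2
  expect_lt(abs(r2 - oracle), 0.5)
  expect_equal(explained_variance(nf, g, "additive", 0), 0)
  # design arithmetic: beta 0.5 SD, MAF 0.3 on a unit-variance trait
  expect_equal(100 * 0.5^2 * 2 * 0.3 * 0.7 / 1, 10.5)
})

test_that("the metabolome-wide threshold is the Bonferroni quotient", {
  expect_equal(metabolome_threshold(5e-8, 42), 5e-8 / 42)
  expect_equal(signif(metabolome_threshold(5e-8, 42), 2), 1.2e-9)
  expect_equal(metabolome_threshold(0.05, 1), 0.05)
  expect_error(metabolome_threshold(5e-8, 0), class = "mqtl_invalid_argument")
})

test_that("genomic inflation is calibrated and scales with chi-square", {
  p <- withr::with_seed(12, runif(1e5))
  expect_equal(genomic_inflation(p), 1, tolerance = 0.02)
  chi <- qchisq(p, 1, lower.tail = FALSE) * 1.2
  p_infl <- pchisq(chi, 1, lower.tail = FALSE)
  expect_equal(genomic_inflation(p_infl), 1.2, tolerance = 0.03)
  expect_equal(genomic_inflation(rep(0.5, 200)), 1)
  expect_error(genomic_inflation(runif(50)), class = "mqtl_insufficient_data")
})

test_that("analytic power reproduces the study's design claims", {
  pw_low <- power_additive(2482, 0.30, 0.2, 1.1e-9)
  expect_gte(pw_low, 0.62)
  expect_lt(pw_low, 1)
  pw_high <- power_additive(2482, 0.15, 0.4, 1.1e-9)
  expect_equal(round(100 * pw_high), 100)
  expect_equal(power_additive(1000, 0.3, 0, 0.05), 0.05, tolerance = 1e-12)
  expect_error(power_additive(1000, 0, 0.2, 0.05),
               class = "mqtl_invalid_argument")
  expect_error(power_additive(1000, 0.3, 0.2, 0),
               class = "mqtl_invalid_argument")
})

test_that("missing dosages are mean-imputed and flagged", {
  ph <- simulate_phenotype(fix_ped, fix_K, cfg = sim_config(0, 0, seed = 13))
  nf <- null_model(ph$y, NULL, fix_K, eigen_A = fix_eigen)
  G <- simulate_genotypes(fix_ped, variant_spec(0.3), seed = 14)
  g <- G$dosage[, 1]
  g[1:5] <- NA
  res <- score_test(nf, g)
  expect_match(res$note, "5 missing")
  expect_equal(res$n_used, nrow(fix_ped) - 5)
  expect_false(is.na(res$p))
})
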