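# Shared fixtures, built once per test run.

# mid-sized three-generation pedigree (~400 individuals) with kinship and
# its eigendecomposition, reused across REML / association tests
fix_ped <- simulate_pedigree(30, 2, mean_children = 2.8, seed = 11)
fix_K <- kinship_from_pedigree(fix_ped)
fix_ped <- fix_ped[match(rownames(fix_K), fix_ped$id), ]
fix_eigen <- kinship_eigen(fix_K)

# hand-built pedigree covering the textbook kinship coefficients:
# founders F, M1, M2; C1, C2 full siblings (F x M1); C3 half sibling (F x M2)
fix_ped_hand <- tibble::tibble(
  id = c("F", "M1", "M2", "C1", "C2", "C3"),
  father = c(NA, NA, NA, "F", "F", "F"),
  mother = c(NA, NA, NA, "M1", "M1", "M2"),
  sex = c("male", "female", "female", "male", "female", "male"),
  household = c("hF", "hM1", "hM2", "h1", "h1", "h2"),
  generation = c(0L, 0L, 0L, 1L, 1L, 1L),
  founder = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))

# classical OLS score test used as the K = I oracle throughout:
# U = (g - mean(g))' r with r the OLS residuals of y ~ X, and
# chi2 = U^2 / (var-part * rss / (n - p))
ols_score_test <- function(y, X, g) {
  Xf <- cbind(1, X)
  r <- lm.fit(Xf, y)$residuals
  s2 <- sum(r^2) / (length(y) - ncol(Xf))
  gt <- g - mean(g)
  chi <- sum(gt * r)^2 / (sum(gt^2) * s2)
  pchisq(chi, df = 1, lower.tail = FALSE)
}

# three-peak noiseless deconvolution truth used in several tests
fix_peaks3 <- tibble::tibble(center = c(1.08, 1.095, 1.11), fwhm = 0.01,
                             amplitude = c(1, 0.8, 1.2),
                             eta = c(0.3, 0.6, 0.5))
fix_axis3 <- seq(1.0, 1.2, by = 2e-4)
fix_spec3 <- tibble::tibble(
  ppm = fix_axis3,
  intensity = mqtlkit:::sum_peaks(fix_axis3, fix_peaks3))

# match fitted peaks to true peaks by nearest center
match_peaks <- function(fit, truth) {
  vapply(truth$center, function(cc) which.min(abs(fit$center - cc)),
         integer(1))
}
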