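#' Simulation configuration for heritable metabolite traits
#'
#' Bundles the variance budget and QTL effects used by
#' [simulate_phenotype()]. The trait model is
#' `y = sum(beta_j * g_j) + a + c + e` with polygenic values
#' `a ~ MVN(0, h2 * 2 Phi)`, a household effect `c` shared within household
#' with variance `c2`, and independent residuals, scaled so the trait has
#' unit total variance in expectation. Each QTL contributes
#' `2 p (1 - p) beta^2` to that budget.
#'
#' @param h2 Target narrow-sense heritability (fraction of total variance).
#' @param c2 Target household (sibship) variance fraction.
#' @param qtl Optional tibble with columns `id` (variant id) and `beta`
#'   (per-allele effect in phenotypic SD units).
#' @param seed Optional integer seed used by [simulate_phenotype()].
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(h2 = 0, c2 = 0, qtl = NULL, seed = NULL) {
  if (h2 < 0 || c2 < 0 || h2 + c2 > 1) {
    abort("need h2 >= 0, c2 >= 0 and h2 + c2 <= 1.",
          class = "mqtl_invalid_argument")
  }
  if (!is.null(qtl) && !all(c("id", "beta") %in% names(qtl))) {
    abort("`qtl` needs columns `id` and `beta`.",
          class = "mqtl_invalid_argument")
  }
  structure(list(h2 = h2, c2 = c2, qtl = qtl, seed = seed),
            class = "sim_config")
}

#' Simulate a heritable metabolite phenotype with covariates
#'
#' Draws one quantitative trait on the pedigree under the variance budget in
#' `cfg` (see [sim_config()]), together with covariates emulating an adult
#' population cohort: age (years), sex (from the pedigree), a BMI-like
#' covariate, and a medication flag drawn independently of the trait
#' (downstream exclusion of medicated individuals is exercised as
#' bookkeeping, not as confounding).
#'
#' @param ped Pedigree tibble.
#' @param K Kinship matrix from [kinship_from_pedigree()].
#' @param G Optional `geno_matrix` carrying the QTL variants named in `cfg`.
#' @param cfg A [sim_config()].
#' @return A tibble with columns `id`, `age`, `sex`, `bmi`, `medication`,
#'   `household`, `y` plus attribute `components` (the realized generative
#'   pieces, for testing).
#' @export
simulate_phenotype <- function(ped, K, G = NULL, cfg = sim_config()) {
  n <- nrow(ped)
  stopifnot(nrow(K) == n)
  K <- K[ped$id, ped$id]
  qtl_var <- 0
  beta <- NULL
  if (!is.null(cfg$qtl) && nrow(cfg$qtl) > 0) {
    if (is.null(G)) abort("`cfg$qtl` given but no genotypes `G` supplied.",
                          class = "mqtl_invalid_argument")
    gd <- G$dosage[ped$id, cfg$qtl$id, drop = FALSE]
    p <- colMeans(gd) / 2
    beta <- cfg$qtl$beta
    qtl_var <- sum(2 * p * (1 - p) * beta^2)
  }
  if (cfg$h2 + cfg$c2 + qtl_var > 1 + 1e-12) {
    abort("variance budget h2 + c2 + sum(2p(1-p)beta^2) exceeds 1.",
          class = "mqtl_invalid_argument")
  }
  with_seed_if(cfg$seed, {
    A <- 2 * K
    a <- if (cfg$h2 > 0) {
      ch <- tryCatch(chol(A), error = function(e) NULL)
      z <- rnorm(n)
      if (is.null(ch)) {
        ee <- eigen(A, symmetric = TRUE)
        sqrt(cfg$h2) * as.vector(ee$vectors %*% (sqrt(pmax(ee$values, 0)) * z))
      } else {
        sqrt(cfg$h2) * as.vector(crossprod(ch, z))
      }
    } else rep(0, n)
    hh <- factor(ped$household)
    c_eff <- if (cfg$c2 > 0) {
      u <- rnorm(nlevels(hh), 0, sqrt(cfg$c2))
      u[as.integer(hh)]
    } else rep(0, n)
    g_eff <- if (qtl_var > 0) {
      as.vector(scale(gd, center = TRUE, scale = FALSE) %*% beta)
    } else rep(0, n)
    e <- rnorm(n, 0, sqrt(max(1 - cfg$h2 - cfg$c2 - qtl_var, 0)))
    y <- a + c_eff + g_eff + e
    out <- tibble::tibble(
      id = ped$id,
      age = round(pmin(pmax(rnorm(n, 48, 14), 18), 90), 1),
      sex = ped$sex,
      bmi = round(rnorm(n, 26.3, 4.2), 1),
      medication = runif(n) < 0.12,
      household = ped$household,
      y = y)
    attr(out, "components") <- list(polygenic = a, household = c_eff,
                                    qtl = g_eff, qtl_var = qtl_var)
    out
  })
}
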