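#' Fit the null mixed model for a score-test GWAS
#'
#' Fits `y ~ N(X b, sigma2_g * 2 Phi + sigma2_e * I)` by [reml_fit()]
#' (household excluded by default: the GWAS covariance follows the two-stage
#' polygenic-null practice; set `include_household = TRUE` to diverge) and
#' stores everything the per-variant score test reuses: the GLS residuals
#' `r = y - X b_hat`, an inverse-covariance operator in the eigenbasis of
#' `2 Phi`, and the residual scale `rᵀ V^-1 r / (n - p)`.
#'
#' @param y Trait vector (complete).
#' @param X Covariate matrix (intercept added if absent).
#' @param kinship Kinship matrix aligned with `y`.
#' @param eigen_A Optional precomputed [kinship_eigen()].
#' @param include_household Include a household component in the null
#'   covariance (requires `household`).
#' @param household Household labels, only used when
#'   `include_household = TRUE`.
#' @return Object of class `null_fit`.
#' @export
null_model <- function(y, X = NULL, kinship, eigen_A = NULL,
                       include_household = FALSE, household = NULL) {
  n <- length(y)
  if (nrow(kinship) != n) {
    abort("`y` and `kinship` dimensions do not match.",
          class = "mqtl_invalid_argument")
  }
  ea <- eigen_A %||% kinship_eigen(kinship)
  fit <- reml_fit(y, X, kinship,
                  household = if (include_household) household else NULL,
                  eigen_A = ea)
  X <- if (is.null(X)) matrix(1, n, 1) else as.matrix(X)
  if (!any(apply(X, 2, function(col) all(col == col[1])))) X <- cbind(1, X)
  vc <- fit$varcomp
  w_abs <- vc[["genetic"]] * ea$d + vc[["residual"]]
  if (include_household && vc[["household"]] > 0) {
    # fold the household variance into a dense covariance in the eigenbasis
    hh <- factor(household)
    Z <- matrix(0, n, nlevels(hh))
    Z[cbind(seq_len(n), as.integer(hh))] <- 1
    Zt <- crossprod(ea$U, Z)
  } else {
    Zt <- NULL
  }
  nf <- structure(list(U = ea$U, w = w_abs, Zt = Zt,
                       s2c = if (!is.null(Zt)) vc[["household"]] else 0,
                       X = X, y = y, fit = fit, n = n, p = ncol(X)),
                  class = "null_fit")
  Vi_y <- vinv_mult(nf, y)
  Vi_X <- vinv_mult(nf, X)
  XtViX <- crossprod(X, Vi_X)
  beta <- solve(XtViX, crossprod(Vi_X, y))
  r <- as.vector(y - X %*% beta)
  nf$beta <- as.vector(beta)
  nf$resid <- r
  nf$Vi_r <- as.vector(Vi_y - Vi_X %*% beta)
  nf$Vi_one <- vinv_mult(nf, rep(1, n))
  nf$sum_Vi_one <- sum(nf$Vi_one)
  nf$sigma2_r <- sum(r * nf$Vi_r) / (n - ncol(X))
  nf$Vi_X <- Vi_X
  nf$XtViX <- XtViX
  nf
}

# apply V^-1 to a vector/matrix via the eigenbasis (+ Woodbury when a
# household component is present)
vinv_mult <- function(nf, M) {
  M <- as.matrix(M)
  Mt <- crossprod(nf$U, M)
  if (is.null(nf$Zt)) {
    Rt <- Mt / nf$w
  } else {
    Wt <- Mt / nf$w
    C <- diag(1 / nf$s2c, ncol(nf$Zt)) + crossprod(nf$Zt, nf$Zt / nf$w)
    Rt <- Wt - (nf$Zt / nf$w) %*% solve(C, crossprod(nf$Zt, Wt))
  }
  nf$U %*% Rt
}

#' @exportS3Method base::print
print.null_fit <- function(x, ...) {
  cat("<null_fit> n =", x$n, "| h2 =", round(x$fit$h2, 3),
      "| sigma2_r =", round(x$sigma2_r, 4), "\n")
  invisible(x)
}

# genotype codings for mode-of-inheritance models
code_genotype <- function(g, coding) {
  switch(coding,
         additive = g,
         dominant = as.numeric(g >= 1),
         recessive = as.numeric(g >= 2),
         overdominant = as.numeric(g == 1),
         abort(paste("unknown coding:", coding),
               class = "mqtl_invalid_argument"))
}

#' Mixed-model score test for one variant
#'
#' Family-based association score test: with `g~` the coded genotype
#' centered at its `V^-1`-weighted mean, the score is `U = g~ᵀ V^-1 r` with
#' `r` the null-model GLS residuals, and the test statistic
#' `chi2 = U^2 / (g~ᵀ V^-1 g~ * s2r)` is compared to chi-square with 1 df
#' (`s2r = rᵀV^-1r / (n - p)` is the residual scale of the null fit). The
#' effect estimate is `beta = U / (g~ᵀ V^-1 g~)`, in trait units per
#' coded-allele unit. Missing dosages are mean-imputed (and flagged).
#'
#' @param nf A `null_fit`.
#' @param g Dosage vector aligned with the null fit samples.
#' @param coding One of `"additive"`, `"dominant"`, `"recessive"`,
#'   `"overdominant"`; non-additive codings are applied to hard calls
#'   (dosages rounded; calls with `|dosage - round| > 0.1` set missing).
#' @param id Variant id carried into the result.
#' @return One-row tibble: `id`, `model`, `beta`, `se`, `chisq`, `p`,
#'   `n_used`, `ea_freq`, `maf`, `note`.
#' @export
score_test <- function(nf, g, coding = "additive", id = NA_character_) {
  g <- as.numeric(g)
  if (length(g) != nf$n) {
    abort("genotype vector length does not match the null fit.",
          class = "mqtl_invalid_argument")
  }
  note <- ""
  if (coding != "additive") {
    hard <- round(g)
    bad <- abs(g - hard) > 0.1
    if (any(bad, na.rm = TRUE)) {
      hard[bad] <- NA
      note <- sprintf("%d uncertain dosages set missing;", sum(bad,
                                                               na.rm = TRUE))
    }
    g <- code_genotype(hard, coding)
  }
  n_miss <- sum(is.na(g))
  ea_freq <- mean(g, na.rm = TRUE) / if (coding == "additive") 2 else 1
  if (n_miss > 0) {
    g[is.na(g)] <- mean(g, na.rm = TRUE)
    note <- paste(note, sprintf("%d missing mean-imputed", n_miss))
  }
  if (sd(g) == 0) {
    return(tibble::tibble(id = id, model = coding, beta = NA_real_,
                          se = NA_real_, chisq = NA_real_, p = NA_real_,
                          n_used = nf$n - n_miss, ea_freq = ea_freq,
                          maf = min(ea_freq, 1 - ea_freq),
                          note = "monomorphic coded genotype"))
  }
  mu <- sum(g * nf$Vi_one) / nf$sum_Vi_one
  gt <- g - mu
  U <- sum(gt * nf$Vi_r)
  den <- sum(gt * vinv_mult(nf, gt))
  chisq <- U^2 / (den * nf$sigma2_r)
  beta <- U / den
  se <- sqrt(nf$sigma2_r / den)
  tibble::tibble(id = id, model = coding, beta = beta, se = se,
                 chisq = chisq, p = pchisq(chisq, 1, lower.tail = FALSE),
                 n_used = nf$n - n_miss, ea_freq = ea_freq,
                 maf = min(ea_freq, 1 - ea_freq),
                 note = trimws(note))
}

#' Score-test GWAS over a genotype matrix
#'
#' Vectorized additive-model scan: equivalent to calling [score_test()] per
#' variant but computed with one matrix rotation into the eigenbasis.
#'
#' @param nf A `null_fit` (without household component).
#' @param G A `geno_matrix` or bare samples x variants dosage matrix.
#' @return Tibble with one row per variant: the [score_test()] columns plus
#'   variant metadata when available.
#' @export
run_gwas <- function(nf, G) {
  d <- if (inherits(G, "geno_matrix")) G$dosage else as.matrix(G)
  if (nrow(d) != nf$n) abort("sample mismatch between genotypes and null fit.",
                             class = "mqtl_invalid_argument")
  if (!is.null(nf$Zt)) {
    # household-augmented covariance: fall back to the per-variant path
    res <- purrr::map_dfr(seq_len(ncol(d)), function(j)
      score_test(nf, d[, j], id = colnames(d)[j]))
    return(res)
  }
  # mean-impute missing dosages per variant
  if (anyNA(d)) {
    mns <- colMeans(d, na.rm = TRUE)
    ij <- which(is.na(d), arr.ind = TRUE)
    d[ij] <- mns[ij[, 2]]
  }
  Gt <- crossprod(nf$U, d)                     # n x m rotation (one gemm)
  v1 <- crossprod(nf$U, rep(1, nf$n)) / nf$w   # U'1 / w
  one_norm <- nf$sum_Vi_one
  mu <- as.vector(crossprod(Gt, v1)) / one_norm
  u1 <- as.vector(crossprod(nf$U, rep(1, nf$n)))
  # centered rotated genotypes: Gt - outer(u1, mu)
  rt_w <- as.vector(crossprod(nf$U, nf$resid)) / nf$w
  num <- as.vector(crossprod(Gt, rt_w)) - mu * sum(u1 * rt_w)
  den <- colSums(Gt^2 / nf$w) - 2 * mu * as.vector(crossprod(Gt, u1 / nf$w)) +
    mu^2 * sum(u1^2 / nf$w)
  ok <- den > 1e-12
  chisq <- ifelse(ok, num^2 / (den * nf$sigma2_r), NA_real_)
  beta <- ifelse(ok, num / den, NA_real_)
  se <- ifelse(ok, sqrt(nf$sigma2_r / den), NA_real_)
  ea_freq <- unname(colMeans(d) / 2)
  beta <- unname(beta); se <- unname(se); chisq <- unname(chisq)
  out <- tibble::tibble(
    id = colnames(d) %||% sprintf("v%d", seq_len(ncol(d))),
    model = "additive", beta = beta, se = se, chisq = chisq,
    p = pchisq(chisq, 1, lower.tail = FALSE),
    n_used = nf$n, ea_freq = ea_freq, maf = pmin(ea_freq, 1 - ea_freq),
    note = ifelse(ok, "", "monomorphic coded genotype"))
  if (inherits(G, "geno_matrix")) {
    meta <- G$variants[c("id", "chr", "pos", "ea", "oa")]
    out <- dplyr::left_join(out, meta, by = "id")
    out <- dplyr::relocate(out, "chr", "pos", "ea", "oa", .after = "id")
  }
  out
}

#' Mode-of-inheritance scan for one variant
#'
#' Tests a hard-called genotype under additive (`0,1,2`), dominant
#' (`0,1,1`), recessive (`0,0,1`) and over-dominant (`0,1,0`) codings of the
#' effect allele and reports the model with the smallest p-value. Codings
#' that collapse to a constant (e.g. no homozygous carriers) are skipped
#' with a reason.
#'
#' @param nf A `null_fit`.
#' @param g Genotype vector; dosages are hard-called as in [score_test()].
#' @param models Codings to test.
#' @param id Variant id.
#' @return Tibble with one row per attempted model and a logical `best`
#'   column marking the smallest p-value.
#' @export
genotype_model_scan <- function(nf, g,
                                models = c("additive", "dominant",
                                           "recessive", "overdominant"),
                                id = NA_character_) {
  res <- purrr::map_dfr(models, function(mo) score_test(nf, g, mo, id = id))
  res$best <- FALSE
  if (any(!is.na(res$p))) {
    res$best[which.min(res$p)] <- TRUE
  }
  res
}

#' Trait variance explained by one variant
#'
#' `R^2 = 100 * beta^2 * Var(coded g) / Var(y residualized on covariates)`,
#' in percent.
#'
#' @param nf A `null_fit` (its covariate-adjusted residuals define the trait
#'   variance).
#' @param g Dosage vector.
#' @param coding Genotype coding.
#' @param beta Effect estimate on the coded scale (from [score_test()]).
#' @return R-squared in percent.
#' @export
explained_variance <- function(nf, g, coding = "additive", beta) {
  gc <- if (coding == "additive") as.numeric(g) else
    code_genotype(round(as.numeric(g)), coding)
  gc[is.na(gc)] <- mean(gc, na.rm = TRUE)
  vy <- var(nf$resid)
  if (vy <= 0) abort("zero trait variance.", class = "mqtl_invalid_argument")
  100 * beta^2 * var(gc) / vy
}

#' Metabolome-wide significance threshold
#'
#' Genome-wide level additionally Bonferroni-corrected for the number of
#' (unique) metabolites tested: `alpha_gw / n_metabolites`.
#'
#' @param alpha_gw Genome-wide significance level (default 5e-8).
#' @param n_metabolites Number of unique metabolites.
#' @return The corrected threshold.
#' @export
#' @examples
#' metabolome_threshold(5e-8, 42)  # 1.19e-9
metabolome_threshold <- function(alpha_gw = 5e-8, n_metabolites) {
  if (!is.numeric(n_metabolites) || n_metabolites < 1) {
    abort("`n_metabolites` must be a positive count.",
          class = "mqtl_invalid_argument")
  }
  alpha_gw / n_metabolites
}

#' Genomic inflation factor
#'
#' `lambda = median(chi2) / qchisq(0.5, 1)` with the chi-square equivalents
#' of the p-values (1 df).
#'
#' @param p Vector of p-values (>= 100 required).
#' @return Lambda (numeric scalar).
#' @export
genomic_inflation <- function(p) {
  p <- p[!is.na(p)]
  if (length(p) < 100) {
    abort("need at least 100 p-values for lambda.",
          class = "mqtl_insufficient_data")
  }
  chi <- qchisq(p, df = 1, lower.tail = FALSE)
  median(chi) / qchisq(0.5, df = 1)
}

#' Analytic power of the additive test
#'
#' Two-sided chi-square (1 df) power for a bi-allelic additive variant: the
#' non-centrality is `NCP = n * 2 * maf * (1 - maf) * beta^2` (beta in
#' phenotypic SD per allele, trait standardized), and
#' `power = P(chisq_1(NCP) > chisq critical at alpha)`.
#'
#' @param n Sample size.
#' @param maf Minor allele frequency in (0, 0.5].
#' @param beta Per-allele effect in SD units.
#' @param alpha Significance level in (0, 1).
#' @return Power as a fraction in \[0, 1\].
#' @export
#' @examples
#' power_additive(2482, 0.30, 0.2, 1.1e-9)
power_additive <- function(n, maf, beta, alpha) {
  if (!is.numeric(maf) || maf <= 0 || maf > 0.5 ||
      !is.numeric(alpha) || alpha <= 0 || alpha >= 1 || n <= 0) {
    abort("invalid `n`, `maf` or `alpha`.", class = "mqtl_invalid_argument")
  }
  ncp <- n * 2 * maf * (1 - maf) * beta^2
  crit <- qchisq(alpha, df = 1, lower.tail = FALSE)
  pchisq(crit, df = 1, ncp = ncp, lower.tail = FALSE)
}
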