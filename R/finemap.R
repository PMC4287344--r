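#' Filter sequence variants by observation count
#'
#' Removes variants observed in fewer than `min_obs` samples, where the
#' observation count is the number of samples carrying at least one copy of
#' the minor allele with non-missing genotype. A variant with exactly
#' `min_obs` observations is retained ("fewer than" are removed).
#'
#' @param gm A `geno_matrix` (dosages may contain `NA`).
#' @param min_obs Minimum number of minor-allele carriers; default 5.
#' @return The filtered `geno_matrix`; attribute `removed` holds the removal
#'   log (id, obs_count).
#' @export
filter_variants <- function(gm, min_obs = 5) {
  d <- gm$dosage
  obs <- vapply(seq_len(ncol(d)), function(j) {
    g <- d[, j]
    g <- g[!is.na(g)]
    if (!length(g)) return(0L)
    f <- mean(g) / 2
    minor <- if (f <= 0.5) g else 2 - g
    sum(round(minor) >= 1)
  }, integer(1))
  keep <- obs >= min_obs
  out <- structure(list(dosage = d[, keep, drop = FALSE],
                        variants = gm$variants[keep, ]),
                   class = "geno_matrix")
  out$variants$obs_count <- obs[keep]
  attr(out, "removed") <- tibble::tibble(id = gm$variants$id[!keep],
                                         obs_count = obs[!keep])
  out
}

#' Linkage disequilibrium r-squared between two dosage vectors
#'
#' Squared Pearson correlation of allele dosages over complete pairs
#' (composite LD; no phasing required).
#'
#' @param gA,gB Dosage vectors.
#' @return r-squared in \[0, 1\].
#' @export
ld_r2 <- function(gA, gB) {
  cc <- stats::complete.cases(gA, gB)
  a <- gA[cc]; b <- gB[cc]
  if (sd(a) == 0 || sd(b) == 0) {
    abort("LD undefined for a constant dosage vector.",
          class = "mqtl_undefined_ld")
  }
  cor(a, b)^2
}

# Score test of g against a null with extra fixed effects, under the fixed
# covariance of `nf`. The tested genotype is residualized on the full fixed-
# effect set under the V^-1 inner product (exact conditional score test).
score_test_adjusted <- function(nf, g, extra) {
  g <- as.numeric(g)
  g[is.na(g)] <- mean(g, na.rm = TRUE)
  Xc <- cbind(nf$X, extra)
  Vi_Xc <- vinv_mult(nf, Xc)
  XtViX <- crossprod(Xc, Vi_Xc)
  # residuals of y on the augmented fixed effects (variance kept fixed)
  y <- nf$y
  beta <- solve(XtViX, crossprod(Vi_Xc, y))
  r <- as.vector(y - Xc %*% beta)
  Vi_r <- vinv_mult(nf, r)
  # project g on the augmented fixed effects under V^-1
  gproj <- solve(XtViX, crossprod(Vi_Xc, g))
  gs <- as.vector(g - Xc %*% gproj)
  den <- sum(gs * vinv_mult(nf, gs))
  if (den < 1e-12) {
    return(tibble::tibble(beta = NA_real_, se = NA_real_, chisq = NA_real_,
                          p = NA_real_))
  }
  U <- sum(gs * Vi_r)
  s2r <- sum(r * Vi_r) / (nf$n - ncol(Xc))
  chisq <- U^2 / (den * s2r)
  tibble::tibble(beta = U / den, se = sqrt(s2r / den), chisq = chisq,
                 p = pchisq(chisq, 1, lower.tail = FALSE))
}

#' Reciprocal conditional association of a variant and a lead SNP
#'
#' Computes the marginal association of the variant, the variant's
#' association adjusted for the lead SNP (lead added to the null-model fixed
#' effects; variance components kept from the null fit), the symmetric
#' lead-adjusted-for-variant p-value, and the LD r-squared, then classifies
#' the pair with [classify_signal()]. Near-collinear pairs
#' (r2 > 0.999) are declared `indistinguishable` with adjusted p-values
#' suppressed.
#'
#' @param nf A `null_fit` built with the trait (see [null_model()]).
#' @param g_v Variant dosage vector.
#' @param g_l Lead SNP dosage vector.
#' @param variant_id,lead_id Ids carried into the result.
#' @param alpha_keep,alpha_drop Classification thresholds (see
#'   [classify_signal()]).
#' @return One-row tibble: `variant_id`, `lead_id`, `beta`, `se`,
#'   `p_marginal`, `p_variant_adj`, `p_lead_adj`, `r2`, `classification`.
#' @export
conditional_pair <- function(nf, g_v, g_l, variant_id = "variant",
                             lead_id = "lead", alpha_keep = 1e-3,
                             alpha_drop = 0.05) {
  if (is.null(nf$y)) nf$y <- nf$resid + nf$X %*% nf$beta
  if (sd(g_v, na.rm = TRUE) == 0 || sd(g_l, na.rm = TRUE) == 0) {
    abort("variant and lead must be non-constant.",
          class = "mqtl_invalid_argument")
  }
  marg <- score_test(nf, g_v, id = variant_id)
  r2 <- ld_r2(g_v, g_l)
  if (r2 > 0.999) {
    return(tibble::tibble(variant_id = variant_id, lead_id = lead_id,
                          beta = marg$beta, se = marg$se,
                          p_marginal = marg$p, p_variant_adj = NA_real_,
                          p_lead_adj = NA_real_, r2 = r2,
                          classification = "indistinguishable"))
  }
  gv <- as.numeric(g_v); gv[is.na(gv)] <- mean(gv, na.rm = TRUE)
  gl <- as.numeric(g_l); gl[is.na(gl)] <- mean(gl, na.rm = TRUE)
  va <- score_test_adjusted(nf, gv, extra = cbind(lead = gl))
  la <- score_test_adjusted(nf, gl, extra = cbind(variant = gv))
  tibble::tibble(
    variant_id = variant_id, lead_id = lead_id,
    beta = marg$beta, se = marg$se, p_marginal = marg$p,
    p_variant_adj = va$p, p_lead_adj = la$p, r2 = r2,
    classification = classify_signal(va$p, la$p, alpha_keep, alpha_drop))
}

#' Classify a conditional-association pattern
#'
#' Using the variant-adjusted p-value `p_variant_adj` (the variant tested
#' with the lead in the model) and the reciprocal `p_lead_adj`:
#' `explains_lead` when the variant survives adjustment while the lead
#' collapses (`p_variant_adj < alpha_keep`, `p_lead_adj >= alpha_drop`);
#' `independent` when both survive (`p_variant_adj < alpha_keep`,
#' `p_lead_adj < alpha_keep`); `tagged_by_lead` when the variant adds
#' nothing over the lead (`p_variant_adj >= alpha_drop`); anything else is
#' `indeterminate`. `NA` adjusted p-values give `indistinguishable`.
#'
#' @param p_variant_adj,p_lead_adj Adjusted p-values (vectorized).
#' @param alpha_keep Significance level a variant must beat to be kept
#'   (default 1e-3).
#' @param alpha_drop Level above which a signal counts as collapsed
#'   (default 0.05).
#' @return Character vector of classifications.
#' @export
#' @examples
#' classify_signal(8.07e-9, 4.05e-1)   # explains_lead
#' classify_signal(2.55e-5, 6.34e-22)  # independent
classify_signal <- function(p_variant_adj, p_lead_adj, alpha_keep = 1e-3,
                            alpha_drop = 0.05) {
  dplyr::case_when(
    is.na(p_variant_adj) | is.na(p_lead_adj) ~ "indistinguishable",
    p_variant_adj < alpha_keep & p_lead_adj >= alpha_drop ~ "explains_lead",
    p_variant_adj < alpha_keep & p_lead_adj < alpha_keep ~ "independent",
    p_variant_adj >= alpha_drop ~ "tagged_by_lead",
    TRUE ~ "indeterminate")
}

#' Fine-map a locus against a lead GWAS SNP
#'
#' Runs [filter_variants()], then [conditional_pair()] for every remaining
#' variant against the lead SNP, and attaches proxy lists (other variants at
#' r2 >= 0.8 with each variant). Output columns mirror a conditional
#' fine-mapping table: alleles, marginal beta / SE / p, MAF, both adjusted
#' p-values, LD with the lead and the classification.
#'
#' @param nf A `null_fit` for the trait (its samples must match `gm`).
#' @param gm `geno_matrix` of sequence variants (may include the lead).
#' @param lead_id Id of the lead GWAS SNP; its dosages must be either a
#'   column of `gm` or supplied via `g_lead`.
#' @param g_lead Optional dosage vector for the lead SNP.
#' @param min_obs Carrier-count filter threshold.
#' @param alpha_keep,alpha_drop Classification thresholds.
#' @return Tibble with one row per variant.
#' @export
finemap_locus <- function(nf, gm, lead_id, g_lead = NULL, min_obs = 5,
                          alpha_keep = 1e-3, alpha_drop = 0.05) {
  if (is.null(g_lead)) {
    if (!lead_id %in% colnames(gm$dosage)) {
      abort("lead SNP not found in genotype matrix.",
            class = "mqtl_key_error")
    }
    g_lead <- gm$dosage[, lead_id]
  }
  fg <- filter_variants(gm, min_obs = min_obs)
  ids <- setdiff(fg$variants$id, lead_id)
  res <- purrr::map_dfr(ids, function(v) {
    cp <- conditional_pair(nf, fg$dosage[, v], g_lead, variant_id = v,
                           lead_id = lead_id, alpha_keep = alpha_keep,
                           alpha_drop = alpha_drop)
    cp
  })
  # proxies: other filtered variants in strong LD with each variant
  prox <- vapply(ids, function(v) {
    others <- setdiff(ids, v)
    r2s <- vapply(others, function(o) {
      tryCatch(ld_r2(fg$dosage[, v], fg$dosage[, o]),
               error = function(e) 0)
    }, numeric(1))
    paste(others[r2s >= 0.8], collapse = ",")
  }, character(1))
  meta <- fg$variants[match(ids, fg$variants$id),
                      intersect(c("id", "chr", "pos", "ea", "oa", "maf",
                                  "function_label", "obs_count"),
                                names(fg$variants))]
  names(meta)[1] <- "variant_id"
  out <- dplyr::left_join(res, meta, by = "variant_id")
  out$proxies <- unname(prox)
  out
}

#' Simulate a two-variant fine-mapping locus
#'
#' Generates unlinked samples with a small LD block and a trait, under one
#' of two architectures: `"causal_tag"` (one causal variant plus a tag in
#' LD with it; the tag is the lead) or `"two_causal"` (two unlinked causal
#' variants; the first is the lead). The tag's allele frequency is chosen so
#' the dosage r-squared with the causal variant hits `r2_target` in
#' expectation (nested-haplotype construction).
#'
#' @param n Sample size.
#' @param architecture `"causal_tag"` or `"two_causal"`.
#' @param beta Per-allele effect (SD units) of the causal variant(s).
#' @param maf Causal-variant minor allele frequency.
#' @param r2_target Target LD between causal variant and tag
#'   (`causal_tag` only).
#' @param seed Optional integer seed.
#' @return List: `geno` (`geno_matrix`), `pheno` (tibble with `id`, `y`,
#'   `age`, `sex`), `lead_id`, `causal_ids`, `architecture`.
#' @export
simulate_locus <- function(n = 2000,
                           architecture = c("causal_tag", "two_causal"),
                           beta = 0.6, maf = 0.2, r2_target = 0.85,
                           seed = NULL) {
  architecture <- match.arg(architecture)
  with_seed_if(seed, {
    ids <- sprintf("S%04d", seq_len(n))
    if (architecture == "causal_tag") {
      # nested haplotypes: tag allele on a superset of causal haplotypes
      m_t <- maf / (r2_target * (1 - maf) + maf)
      h_causal <- runif(2 * n) < maf
      h_tag <- h_causal | (runif(2 * n) < (m_t - maf) / (1 - maf) & !h_causal)
      dim(h_causal) <- dim(h_tag) <- c(n, 2)
      d <- cbind(causal = rowSums(h_causal), tag = rowSums(h_tag))
      causal <- "causal"; lead <- "tag"
      betas <- c(causal = beta)
    } else {
      d <- cbind(causal1 = rbinom(n, 2, maf), causal2 = rbinom(n, 2, 0.25))
      causal <- c("causal1", "causal2"); lead <- "causal1"
      betas <- c(causal1 = beta, causal2 = beta)
    }
    rownames(d) <- ids
    ea_freq <- colMeans(d) / 2
    vt <- tibble::tibble(id = colnames(d), chr = 1L,
                         pos = seq_len(ncol(d)) * 1000L,
                         maf = pmin(ea_freq, 1 - ea_freq), block = "locus",
                         ea = "A", oa = "G", ea_freq = ea_freq)
    gm <- structure(list(dosage = d, variants = vt), class = "geno_matrix")
    gvar <- sum(2 * ea_freq[causal] * (1 - ea_freq[causal]) * betas[causal]^2)
    y <- as.vector(scale(d[, causal, drop = FALSE], scale = FALSE) %*%
                     betas[causal]) +
      rnorm(n, 0, sqrt(max(1 - gvar, 0.1)))
    pheno <- tibble::tibble(id = ids, age = rnorm(n, 48, 14),
                            sex = sample(c("male", "female"), n, TRUE),
                            y = y)
    list(geno = gm, pheno = pheno, lead_id = lead, causal_ids = causal,
         architecture = architecture)
  })
}
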