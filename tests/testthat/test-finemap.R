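make_geno <- function(d) {
  ea <- colMeans(d, na.rm = TRUE) / 2
  vt <- tibble::tibble(id = as.character(colnames(d)), chr = 1L,
                       pos = seq_len(ncol(d)) * 100L,
                       maf = pmin(ea, 1 - ea), block = NA_character_,
                       ea = "A", oa = "G", ea_freq = ea)
  structure(list(dosage = d, variants = vt), class = "geno_matrix")
}

test_that("variants with fewer than five carriers are removed", {
  set.seed(1)
  n <- 200
  d <- cbind(rare4 = c(rep(1, 4), rep(0, n - 4)),
             rare5 = c(rep(1, 5), rep(0, n - 5)),
             common = rbinom(n, 2, 0.3))
  rownames(d) <- sprintf("s%03d", 1:n)
  fg <- filter_variants(make_geno(d), min_obs = 5)
  expect_equal(fg$variants$id, c("rare5", "common"))
  expect_equal(attr(fg, "removed")$id, "rare4")
  expect_equal(attr(fg, "removed")$obs_count, 4L)
  # empty table passes through
  fe <- filter_variants(make_geno(d[, 0, drop = FALSE]))
  expect_equal(ncol(fe$dosage), 0)
})

test_that("carrier counting folds to the minor allele", {
  n <- 100
  # effect allele nearly fixed: minor allele = reference, 3 carriers
  d <- cbind(flip = c(rep(1, 3), rep(2, n - 3)))
  rownames(d) <- sprintf("s%03d", 1:n)
  fg <- filter_variants(make_geno(d), min_obs = 5)
  expect_equal(ncol(fg$dosage), 0)
})

test_that("LD r2 is a squared dosage correlation with its symmetries", {
  set.seed(2)
  g <- rbinom(1000, 2, 0.3)
  expect_equal(ld_r2(g, g), 1)
  h <- rbinom(1000, 2, 0.3)
  expect_equal(ld_r2(g, h), ld_r2(h, g))
  expect_lt(ld_r2(g, h), 0.01 + 3 / 1000)
  expect_error(ld_r2(g, rep(1, 1000)), class = "mqtl_undefined_ld")
})

test_that("classification reproduces the conditional-analysis patterns", {
  # values as printed for a tagged-causal missense variant and an
  # independent intronic signal
  expect_equal(classify_signal(8.07e-9, 4.05e-1), "explains_lead")
  expect_equal(classify_signal(2.55e-5, 6.34e-22), "independent")
  expect_equal(classify_signal(0.5, 1e-20), "tagged_by_lead")
  expect_equal(classify_signal(NA, 0.5), "indistinguishable")
  expect_equal(classify_signal(1e-4, 0.01), "indeterminate")
})

test_that("classification is monotone in the variant-adjusted p-value", {
  p_lead <- c(0.5, 0.01, 1e-6)
  for (pl in p_lead) {
    cls <- classify_signal(10^seq(-12, -0.01, length.out = 40), pl)
    tagged <- cls == "tagged_by_lead"
    # once a variant is non-tagged at some p, smaller p never re-tags it
    expect_true(all(diff(as.integer(tagged)) >= 0))
  }
})

test_that("identical variant and lead are indistinguishable", {
  set.seed(3)
  n <- 400
  g <- rbinom(n, 2, 0.3)
  y <- 0.3 * g + rnorm(n)
  nf <- null_model(y, NULL, diag(0.5, n))
  cp <- conditional_pair(nf, g, g)
  expect_equal(cp$classification, "indistinguishable")
  expect_true(is.na(cp$p_variant_adj))
  expect_equal(cp$r2, 1)
  expect_error(conditional_pair(nf, rep(0, n), g),
               class = "mqtl_invalid_argument")
})

test_that("conditioning on an unlinked lead leaves the p-value unchanged", {
  set.seed(4)
  n <- 1000
  g <- rbinom(n, 2, 0.3)
  lead <- rbinom(n, 2, 0.2)
  y <- 0.25 * (g - mean(g)) + rnorm(n)
  nf <- null_model(y, NULL, diag(0.5, n))
  cp <- conditional_pair(nf, g, lead)
  expect_lt(abs(log10(cp$p_variant_adj) - log10(cp$p_marginal)), 0.6)
  expect_lt(cp$r2, 0.02)
})

test_that("causal-plus-tag loci yield the explains-lead pattern", {
  hits <- vapply(1:25, function(s) {
    loc <- simulate_locus(2000, "causal_tag", beta = 0.5, maf = 0.2,
                          r2_target = 0.9, seed = 400 + s)
    nf <- null_model(loc$pheno$y, NULL, diag(0.5, 2000))
    cp <- conditional_pair(nf, loc$geno$dosage[, "causal"],
                           loc$geno$dosage[, "tag"])
    cp$p_variant_adj < 0.05 && cp$p_lead_adj > 0.05
  }, logical(1))
  expect_gte(sum(hits), 22)  # >= ~90% of seeds
})

test_that("two independent causal variants both survive conditioning", {
  loc <- simulate_locus(2000, "two_causal", beta = 0.4, seed = 5)
  nf <- null_model(loc$pheno$y, NULL, diag(0.5, 2000))
  cp <- conditional_pair(nf, loc$geno$dosage[, "causal2"],
                         loc$geno$dosage[, "causal1"])
  expect_equal(cp$classification, "independent")
  expect_lt(cp$r2, 0.05)
})

test_that("locus-wide fine-mapping returns the full reporting table", {
  loc <- simulate_locus(1500, "causal_tag", seed = 6)
  nf <- null_model(loc$pheno$y, NULL, diag(0.5, 1500))
  tab <- finemap_locus(nf, loc$geno, lead_id = loc$lead_id)
  expect_true(all(c("variant_id", "lead_id", "beta", "se", "p_marginal",
                    "p_variant_adj", "p_lead_adj", "r2", "classification",
                    "maf", "proxies") %in% names(tab)))
  expect_equal(tab$variant_id, "causal")
  expect_true(all(tab$p_marginal > 0 & tab$p_marginal <= 1, na.rm = TRUE))
})

test_that("locus simulation hits its LD target", {
  loc <- simulate_locus(20000, "causal_tag", maf = 0.2, r2_target = 0.85,
                        seed = 7)
  r2 <- ld_r2(loc$geno$dosage[, "causal"], loc$geno$dosage[, "tag"])
  expect_equal(r2, 0.85, tolerance = 0.05)
})
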