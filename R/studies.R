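#' Reference simulation studies
#'
#' These functions run the package's standard self-validation experiments at
#' the study scale described in the methods vignette: heritability recovery,
#' score-test calibration, deconvolution recovery, end-to-end metabolite
#' quantification, fine-mapping architecture recovery, and
#' mode-of-inheritance recovery. Each takes a single integer seed from which
#' all per-replicate seeds are derived, so a study is reproducible from one
#' number.
#'
#' @name studies
NULL

# cohort-scale pedigree used across the studies (~2,000 individuals,
# three generations descending from 120 founder couples)
study_pedigree <- function(seed) {
  ped <- simulate_pedigree(120, 2, mean_children = 2.8, seed = seed)
  K <- kinship_from_pedigree(ped)
  ped <- ped[match(rownames(K), ped$id), ]
  list(ped = ped, K = K)
}

#' @describeIn studies Simulate pedigrees with h2 = 0.4, c2 = 0.05 traits
#'   and refit them by REML; reports mean absolute errors of the ratio
#'   estimates.
#' @param n_reps Number of replicate pedigrees.
#' @param seed Base seed.
#' @param h2,c2 Generating variance fractions.
#' @return A list of summary statistics (see each study's fields).
#' @export
study_heritability_recovery <- function(n_reps = 10, seed = 1, h2 = 0.4,
                                        c2 = 0.05) {
  est <- vapply(seq_len(n_reps), function(r) {
    sp <- study_pedigree(child_seed(seed, r))
    ph <- simulate_phenotype(sp$ped, sp$K,
                             cfg = sim_config(h2, c2,
                                              seed = child_seed(seed,
                                                                1000 + r)))
    fit <- fit_polygenic(ph, "y", c("age", "sex"), sp$K, household = TRUE)
    c(fit$h2, fit$c2)
  }, numeric(2))
  list(h2_estimates = est[1, ], c2_estimates = est[2, ],
       h2_mae = mean(abs(est[1, ] - h2)),
       c2_mae = mean(abs(est[2, ] - c2)),
       n = n_reps)
}

#' @describeIn studies Type-I error and genomic inflation of the mixed-model
#'   score test on one heritable trait and `n_variants` null variants
#'   gene-dropped on the same pedigree, plus the naive-OLS comparison and
#'   the K = I oracle agreement.
#' @param n_variants Number of null variants.
#' @export
study_score_calibration <- function(n_variants = 10000, seed = 1) {
  sp <- study_pedigree(child_seed(seed, 1))
  ph <- simulate_phenotype(sp$ped, sp$K,
                           cfg = sim_config(0.4, 0,
                                            seed = child_seed(seed, 2)))
  X <- covariate_matrix(ph, c("age", "sex"))
  ea <- kinship_eigen(sp$K)
  nf <- null_model(ph$y, X, sp$K, eigen_A = ea)
  r_ols <- lm.fit(cbind(1, X), ph$y)$residuals
  s2_ols <- sum(r_ols^2) / (nrow(sp$ped) - 3)
  chunk <- 1000L
  ps <- numeric(0); ps_ols <- numeric(0)
  for (k in seq_len(ceiling(n_variants / chunk))) {
    m <- min(chunk, n_variants - (k - 1L) * chunk)
    vs <- with_seed_if(child_seed(seed, 100 + k),
                       variant_spec(runif(m, 0.05, 0.5)))
    G <- simulate_genotypes(sp$ped, vs, seed = child_seed(seed, 200 + k))
    ps <- c(ps, run_gwas(nf, G)$p)
    gc_ <- scale(G$dosage, scale = FALSE)
    chi <- as.vector(crossprod(gc_, r_ols))^2 / (colSums(gc_^2) * s2_ols)
    ps_ols <- c(ps_ols, pchisq(chi, 1, lower.tail = FALSE))
  }
  # OLS-oracle equivalence under identity kinship
  n0 <- 500
  y0 <- with_seed_if(child_seed(seed, 3), rnorm(n0))
  X0 <- with_seed_if(child_seed(seed, 4),
                     cbind(age = rnorm(n0, 50, 10)))
  nf0 <- null_model(y0, X0, diag(0.5, n0))
  rel <- vapply(1:50, function(j) {
    g0 <- with_seed_if(child_seed(seed, 300 + j),
                       rbinom(n0, 2, runif(1, 0.1, 0.5)))
    p_mm <- score_test(nf0, g0)$p
    r0 <- lm.fit(cbind(1, X0), y0)$residuals
    s20 <- sum(r0^2) / (n0 - 2)
    gt <- g0 - mean(g0)
    p_ref <- pchisq(sum(gt * r0)^2 / (sum(gt^2) * s20), 1,
                    lower.tail = FALSE)
    abs(p_mm - p_ref) / p_ref
  }, numeric(1))
  list(type1 = mean(ps < 0.05), lambda = genomic_inflation(ps),
       type1_ols = mean(ps_ols < 0.05),
       ols_max_rel_diff = max(rel), n_variants = length(ps),
       n_samples = nrow(sp$ped))
}

# canonical three-peak deconvolution fixture (two of the peaks overlap at
# 1.5x their width)
deconv_fixture <- function() {
  list(truth = tibble::tibble(center = c(1.08, 1.095, 1.11), fwhm = 0.01,
                              amplitude = c(1, 0.8, 1.2),
                              eta = c(0.3, 0.6, 0.5)),
       ppm = seq(1.0, 1.2, by = 2e-4))
}

#' @describeIn studies Deconvolution recovery: noiseless three-peak
#'   parameter recovery and Monte-Carlo amplitude recovery at
#'   signal-to-noise 100.
#' @param n_seeds Number of Monte-Carlo noise replicates.
#' @export
study_deconvolution_recovery <- function(n_seeds = 20, seed = 1) {
  fx <- deconv_fixture()
  clean <- tibble::tibble(ppm = fx$ppm,
                          intensity = sum_peaks(fx$ppm, fx$truth))
  fit <- deconvolute(clean, detect_peaks(clean, 0.05))
  rel_clean <- max(abs(as.matrix(fit[c("center", "fwhm", "amplitude",
                                       "eta")]) -
                         as.matrix(fx$truth)) / abs(as.matrix(fx$truth)))
  amp_err <- vapply(seq_len(n_seeds), function(r) {
    noisy <- tibble::tibble(
      ppm = fx$ppm,
      intensity = sum_peaks(fx$ppm, fx$truth) +
        with_seed_if(child_seed(seed, r), rnorm(length(fx$ppm), 0, 0.01)))
    f <- deconvolute(noisy, detect_peaks(noisy, 0.05))
    if (nrow(f) < 3) return(Inf)
    m <- vapply(fx$truth$center,
                function(cc) which.min(abs(f$center - cc)), integer(1))
    max(abs(f$amplitude[m] - fx$truth$amplitude) / fx$truth$amplitude)
  }, numeric(1))
  list(clean_max_rel_err = rel_clean, snr100_amp_err = amp_err,
       snr100_max_amp_err = max(amp_err), n_seeds = n_seeds)
}

#' @describeIn studies End-to-end quantification: simulate paired spectra at
#'   signal-to-noise ~50, run the full JRES-deconvolution + CPMG-fit
#'   pipeline, and correlate quantified metabolite intensities with the true
#'   concentrations.
#' @param n_samples Number of simulated serum samples.
#' @export
study_endtoend_quantification <- function(n_samples = 30, seed = 1) {
  sig <- example_signatures(5, seed = child_seed(seed, 1))
  mets <- unique(sig$metabolite)
  conc <- with_seed_if(child_seed(seed, 2),
                       matrix(exp(rnorm(n_samples * length(mets), 0, 0.4)),
                              n_samples,
                              dimnames = list(NULL, mets)))
  st <- simulate_spectra(sig, conc, noise_sd_jres = 0.02,
                         noise_sd_cpmg = 0.02, baseline = c(0.02, 0.005),
                         seed = child_seed(seed, 3))
  mj <- mean_spectrum(st, "jres")
  basis <- deconvolute(mj, detect_peaks(mj, 0.03))
  P <- quantify_samples(st, basis)
  grp <- group_peaks(P, 0.8)
  mi <- metabolite_intensities(P, grp)
  truecen <- split(sig$center, sig$metabolite)
  rs <- vapply(mets, function(m) {
    near <- vapply(grp$center,
                   function(cc) min(abs(cc - truecen[[m]])) < 0.005,
                   logical(1))
    if (!any(near)) return(NA_real_)
    g <- names(sort(table(grp$group[near]), decreasing = TRUE))[1]
    cor(mi[[g]], conc[, m])
  }, numeric(1))
  list(cor_per_metabolite = rs, min_cor = min(rs),
       n_peaks = nrow(basis), width_scale = P$width_scale)
}

#' @describeIn studies Fine-mapping architecture recovery over simulated
#'   two-variant loci (alternating causal-plus-tag and two-causal
#'   architectures); reports the fraction classified correctly at the
#'   default thresholds.
#' @param n_loci Number of simulated loci.
#' @export
study_finemap_recovery <- function(n_loci = 100, seed = 1) {
  correct <- vapply(seq_len(n_loci), function(s) {
    arch <- if (s %% 2 == 0) "causal_tag" else "two_causal"
    loc <- simulate_locus(2000, arch,
                          beta = if (arch == "causal_tag") 0.6 else 0.4,
                          seed = child_seed(seed, s))
    nf <- null_model(loc$pheno$y,
                     covariate_matrix(loc$pheno, c("age", "sex")),
                     diag(0.5, 2000))
    if (arch == "causal_tag") {
      cp <- conditional_pair(nf, loc$geno$dosage[, "causal"],
                             loc$geno$dosage[, "tag"])
      cp$classification == "explains_lead"
    } else {
      cp <- conditional_pair(nf, loc$geno$dosage[, "causal2"],
                             loc$geno$dosage[, "causal1"])
      cp$classification == "independent"
    }
  }, logical(1))
  list(accuracy = mean(correct), n_loci = n_loci)
}

#' @describeIn studies Mode-of-inheritance recovery: traits generated with a
#'   purely recessive effect (carriers of two copies shifted by `delta` SD)
#'   on a polygenic background; reports how often the recessive coding wins
#'   the model scan.
#' @param delta Recessive genotype effect in SD units.
#' @param maf Causal-variant minor allele frequency.
#' @export
study_moi_recovery <- function(n_seeds = 100, seed = 1, delta = 0.7,
                               maf = 0.3) {
  sp <- study_pedigree(child_seed(seed, 1))
  ea <- kinship_eigen(sp$K)
  ch <- chol(2 * sp$K)
  n <- nrow(sp$ped)
  h2 <- 0.3
  wins <- vapply(seq_len(n_seeds), function(s) {
    g <- simulate_genotypes(sp$ped, variant_spec(maf),
                            seed = child_seed(seed, 100 + s))$dosage[, 1]
    rec <- as.numeric(g >= 2)
    y <- with_seed_if(child_seed(seed, 1000 + s), {
      a <- sqrt(h2) * as.vector(crossprod(ch, rnorm(n)))
      delta * (rec - mean(rec)) + a +
        rnorm(n, 0, sqrt(max(1 - h2 - delta^2 * var(rec), 0.1)))
    })
    nf <- null_model(y, NULL, sp$K, eigen_A = ea)
    sc <- genotype_model_scan(nf, g)
    sc$model[sc$best] == "recessive"
  }, logical(1))
  list(recessive_best_fraction = mean(wins), n_seeds = n_seeds)
}
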