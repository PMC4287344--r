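test_that("pseudo-Voigt obeys its defining values", {
  for (eta in c(0, 0.3, 1)) {
    expect_equal(pseudo_voigt(2, 2, 0.01, 3, eta), 3)          # height at center
    expect_equal(pseudo_voigt(2.005, 2, 0.01, 3, eta), 1.5)    # half at w/2
  }
  # pure Gaussian one FWHM from center: exp(-4 ln 2) = 1/16
  expect_equal(pseudo_voigt(2.01, 2, 0.01, 1, 0), exp(-4 * log(2)))
  expect_error(pseudo_voigt(2, 2, 0, 1), class = "mqtl_invalid_argument")
  expect_error(pseudo_voigt(2, 2, 0.01, -1), class = "mqtl_invalid_argument")
})

test_that("pseudo-Voigt integrates to the analytic area", {
  for (eta in c(0, 0.4, 1)) {
    num <- stats::integrate(pseudo_voigt, -2, 2, center = 0, fwhm = 0.01,
                            amplitude = 1.3, eta = eta,
                            rel.tol = 1e-9, subdivisions = 2000L)$value
    ana <- pseudo_voigt_area(0.01, 1.3, eta)
    # Lorentzian tails beyond the finite integration range
    expect_equal(num, ana, tolerance = 2e-3)
  }
})

test_that("peak detection finds resolved peaks and respects the threshold", {
  x <- seq(0.5, 1.5, by = 1e-3)
  pk <- tibble::tibble(center = c(0.9, 1.0), fwhm = 0.01, amplitude = 1,
                       eta = 0.5)
  s <- tibble::tibble(ppm = x, intensity = mqtlkit:::sum_peaks(x, pk))
  det <- detect_peaks(s, 0.05)
  expect_equal(nrow(det), 2)
  expect_equal(det$center, c(0.9, 1.0), tolerance = 1.5e-3)
  # constant spectrum: no maxima
  flat <- tibble::tibble(ppm = x, intensity = rep(1, length(x)))
  expect_equal(nrow(detect_peaks(flat, 0.05)), 0)
  # just below / above the prominence threshold (relative to max = 1)
  pk2 <- dplyr::bind_rows(pk, tibble::tibble(center = 1.3, fwhm = 0.01,
                                             amplitude = 0.1, eta = 0.5))
  s2 <- tibble::tibble(ppm = x, intensity = mqtlkit:::sum_peaks(x, pk2))
  expect_equal(nrow(detect_peaks(s2, 0.2)), 2)    # 0.1 < 0.2 threshold
  expect_equal(nrow(detect_peaks(s2, 0.05)), 3)   # 0.1 > 0.05 threshold
  expect_error(detect_peaks(tibble::tibble(ppm = numeric(0),
                                           intensity = numeric(0))),
               class = "mqtl_invalid_argument")
})

test_that("a noiseless single peak is recovered from perturbed initials", {
  x <- seq(1.9, 2.1, by = 2e-4)
  truth <- tibble::tibble(center = 2.0, fwhm = 0.012, amplitude = 1.5,
                          eta = 0.4)
  s <- tibble::tibble(ppm = x, intensity = mqtlkit:::sum_peaks(x, truth))
  init <- tibble::tibble(center = 2.002, fwhm = 0.012 * 1.2,
                         amplitude = 1.5 * 0.8, eta = 0.48)
  fit <- deconvolute(s, init)
  rel <- abs(as.matrix(fit[c("center", "fwhm", "amplitude", "eta")]) -
               as.matrix(truth)) / abs(as.matrix(truth))
  expect_lt(max(rel), 1e-3)
  expect_true(attr(fit, "converged"))
})

test_that("deconvolution never returns a worse residual than its start", {
  s <- fix_spec3
  s$intensity <- s$intensity + withr::with_seed(41, rnorm(nrow(s), 0, 0.02))
  init <- detect_peaks(s, 0.05)
  fit <- deconvolute(s, init, opts = list(max_restarts = 2))
  expect_lte(attr(fit, "rss"), attr(fit, "rss_init"))
  expect_error(deconvolute(s, init[0, ]), class = "mqtl_invalid_argument")
})

test_that("CPMG quantification is exact for the generating shapes", {
  x <- seq(0.5, 2.5, by = 1e-3)
  basis <- tibble::tibble(center = c(1.0, 1.6, 2.1), fwhm = 0.01,
                          amplitude = 1, eta = c(0.2, 0.5, 0.8))
  conc <- c(2, 0.5, 1.2)
  y <- mqtlkit:::sum_peaks(x, dplyr::mutate(basis, amplitude = conc))
  cpmg <- tibble::tibble(ppm = x, intensity = y)
  q <- quantify_cpmg(cpmg, basis, width_scale = 1, baseline_degree = -1)
  expect_equal(q$intensity, conc, tolerance = 1e-8)
  # well-separated peaks: each coefficient is essentially an independent
  # projection (Lorentzian tails leave a ~1e-4 relative coupling)
  q1 <- quantify_cpmg(cpmg, basis[1, ], width_scale = 1,
                      baseline_degree = -1)
  expect_equal(q1$intensity, conc[1], tolerance = 1e-3)
})

test_that("quantification is linear in the spectrum", {
  x <- seq(0.5, 2.5, by = 1e-3)
  basis <- tibble::tibble(center = c(1.0, 1.6), fwhm = 0.01, amplitude = 1,
                          eta = 0.5)
  y <- mqtlkit:::sum_peaks(x, dplyr::mutate(basis, amplitude = c(1.5, 0.7)))
  s1 <- tibble::tibble(ppm = x, intensity = y)
  s3 <- tibble::tibble(ppm = x, intensity = 3 * y)
  q1 <- quantify_cpmg(s1, basis, width_scale = 1, baseline_degree = -1,
                      nonneg = FALSE)
  q3 <- quantify_cpmg(s3, basis, width_scale = 1, baseline_degree = -1,
                      nonneg = FALSE)
  expect_equal(q3$intensity, 3 * q1$intensity, tolerance = 1e-10)
})

test_that("a linear baseline is absorbed by the baseline term only", {
  x <- seq(0.5, 2.5, by = 1e-3)
  basis <- tibble::tibble(center = c(1.0, 1.6), fwhm = 0.01, amplitude = 1,
                          eta = 0.5)
  conc <- c(1.5, 0.7)
  y <- mqtlkit:::sum_peaks(x, dplyr::mutate(basis, amplitude = conc))
  ramp <- 0.3 + 0.2 * x
  s <- tibble::tibble(ppm = x, intensity = y + ramp)
  with_bl <- quantify_cpmg(s, basis, width_scale = 1, baseline_degree = 1)
  without <- quantify_cpmg(s, basis, width_scale = 1, baseline_degree = -1)
  expect_equal(with_bl$intensity, conc, tolerance = 0.01)
  expect_gt(max(abs(without$intensity - conc) / conc), 0.01)
})

test_that("duplicate shapes raise a degenerate-design error", {
  x <- seq(0.5, 1.5, by = 1e-3)
  basis <- tibble::tibble(center = c(1.0, 1.0), fwhm = 0.01, amplitude = 1,
                          eta = 0.5)
  s <- tibble::tibble(ppm = x, intensity = mqtlkit:::sum_peaks(x, basis))
  expect_error(quantify_cpmg(s, basis, width_scale = 1),
               class = "mqtl_degenerate_design")
})

test_that("peak grouping follows the driving concentration series", {
  set.seed(51)
  c1 <- exp(rnorm(30)); c2 <- exp(rnorm(30))
  # peaks 1,2 driven by c1; peak 3 by c2; small measurement noise
  P <- cbind(p1 = c1 * 1.0, p2 = c1 * 0.4, p3 = c2) *
    matrix(exp(rnorm(90, 0, 0.01)), 30)
  grp <- group_peaks(P, 0.8)
  expect_equal(grp$group[1], grp$group[2])
  expect_false(grp$group[1] == grp$group[3])
  # unreachable threshold: every peak its own group
  grp1 <- group_peaks(P, 1 + 1e-9)
  expect_equal(length(unique(grp1$group)), 3)
  expect_error(group_peaks(P[1:2, ]), class = "mqtl_insufficient_data")
})

test_that("spectrum QC flags noise-only and drifting spectra", {
  x <- seq(0.5, 4.5, by = 1e-3)
  noise <- tibble::tibble(ppm = x,
                          intensity = withr::with_seed(61,
                                                       rnorm(length(x), 0, 1)))
  qn <- qc_spectrum(noise, min_snr = 10)
  expect_false(qn$pass)
  expect_match(qn$reasons, "snr")
  clean <- tibble::tibble(ppm = x, intensity = mqtlkit:::sum_peaks(
    x, tibble::tibble(center = 2, fwhm = 0.01, amplitude = 1, eta = 0.5)) +
      withr::with_seed(62, rnorm(length(x), 0, 0.005)))
  expect_true(qc_spectrum(clean, min_snr = 10)$pass)
  ramped <- clean
  ramped$intensity <- ramped$intensity + 2 * (x - 0.5)
  qr_ <- qc_spectrum(ramped, min_snr = 10, max_baseline_drift = 0.2)
  expect_false(qr_$pass)
  expect_match(qr_$reasons, "baseline")
})

test_that("simulated spectra are exact sums without noise and scale linearly", {
  sig <- example_signatures(3, seed = 71)
  conc <- matrix(1, 2, 3, dimnames = list(NULL, unique(sig$metabolite)))
  conc[2, 1] <- 2  # doubled first metabolite in sample 2
  st <- simulate_spectra(sig, conc, ppm = seq(0.5, 4.5, by = 2e-3),
                         noise_sd_jres = 0, noise_sd_cpmg = 0,
                         baseline = c(0, 0), seed = 72)
  mets <- unique(sig$metabolite)
  prof <- vapply(mets, function(m) {
    pk <- sig[sig$metabolite == m, ]
    mqtlkit:::sum_peaks(st$ppm, tibble::tibble(center = pk$center,
                                               fwhm = 0.0035,
                                               amplitude = pk$rel_amplitude,
                                               eta = pk$eta))
  }, numeric(length(st$ppm)))
  expect_equal(st$jres[1, ], unname(rowSums(prof)), tolerance = 1e-12)
  # doubling one metabolite doubles exactly its own peaks
  diff12 <- st$jres[2, ] - st$jres[1, ]
  expect_equal(diff12, unname(prof[, 1]), tolerance = 1e-12)
  expect_error(simulate_spectra(sig, conc * -1),
               class = "mqtl_invalid_argument")
})

test_that("spectrum TSV round trip uses descending ppm on disk", {
  s <- tibble::tibble(ppm = seq(1, 2, by = 0.01),
                      intensity = rnorm(101))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_spectrum_tsv(s, path)
  raw <- readr::read_tsv(path, col_types = "dd", progress = FALSE)
  expect_true(all(diff(raw$ppm) < 0))
  back <- read_spectrum_tsv(path)
  expect_equal(back$ppm, s$ppm)
  expect_equal(back$intensity, s$intensity)
})

test_that("a spike-in raises only the spiked metabolite's quantification", {
  sig <- tibble::tibble(
    metabolite = c("metA", "metB", "metB"),
    center = c(1.2, 2.4, 2.43),
    rel_amplitude = c(1, 0.6, 0.4),
    eta = c(0.4, 0.5, 0.6))
  conc <- matrix(c(1, 1.5, 1, 1), 2, 2,
                 dimnames = list(NULL, c("metA", "metB")))  # +0.5 metA spike
  st <- simulate_spectra(sig, conc, ppm = seq(0.8, 3, by = 5e-4),
                         noise_sd_jres = 1e-3, noise_sd_cpmg = 5e-4,
                         seed = 81)
  basis <- deconvolute(mean_spectrum(st, "jres"),
                       detect_peaks(mean_spectrum(st, "jres"), 0.05))
  P <- quantify_samples(st, basis)
  # identify metA's peak by center, compare sample 2 vs 1
  iA <- which.min(abs(P$peaks$center - 1.2))
  iB <- which.min(abs(P$peaks$center - 2.4))
  dA <- P$intensity[2, iA] - P$intensity[1, iA]
  dB <- P$intensity[2, iB] - P$intensity[1, iB]
  expect_equal(dA, 0.5, tolerance = 0.05)
  expect_lt(abs(dB), 0.05)
})
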