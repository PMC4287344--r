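#' Example metabolite signatures
#'
#' Builds a plausible set of metabolite signatures for simulation: each
#' metabolite owns one to three pseudo-Voigt peaks (a singlet to triplet-like
#' pattern) at well-separated chemical shifts, with relative amplitudes
#' summing to one.
#'
#' @param n_metabolites Number of metabolites.
#' @param seed Optional integer seed.
#' @param ppm_range Chemical-shift range the peak centers are placed in.
#' @return A signature tibble with columns `metabolite`, `center`,
#'   `rel_amplitude`, `eta`.
#' @export
example_signatures <- function(n_metabolites = 5, seed = NULL,
                               ppm_range = c(0.8, 4.2)) {
  with_seed_if(seed, {
    anchors <- seq(ppm_range[1], ppm_range[2],
                   length.out = n_metabolites + 2)[2:(n_metabolites + 1)]
    purrr::map_dfr(seq_len(n_metabolites), function(i) {
      k <- sample(1:3, 1)
      offs <- if (k == 1) 0 else seq(-0.012, 0.012, length.out = k)
      rel <- runif(k, 0.5, 1)
      tibble::tibble(
        metabolite = sprintf("met%02d", i),
        center = anchors[i] + offs,
        rel_amplitude = rel / sum(rel),
        eta = runif(k, 0.2, 0.8))
    })
  })
}

#' Validate a signature table
#'
#' @param sig Signature tibble (`metabolite`, `center`, `rel_amplitude`,
#'   `eta`).
#' @return `sig` invisibly; errors on violations (no peaks, non-positive
#'   relative amplitudes).
#' @export
validate_signatures <- function(sig) {
  req <- c("metabolite", "center", "rel_amplitude", "eta")
  if (!all(req %in% names(sig)) || nrow(sig) == 0) {
    abort("signatures need >= 1 peak and columns metabolite, center, rel_amplitude, eta.",
          class = "mqtl_invalid_argument")
  }
  if (any(sig$rel_amplitude <= 0)) {
    abort("relative amplitudes must be positive.",
          class = "mqtl_invalid_argument")
  }
  invisible(sig)
}

#' Simulate paired CPMG / JRES-projection spectra
#'
#' Each sample's spectrum is the sum over metabolites of concentration times
#' the metabolite's signature peaks, plus a linear baseline and Gaussian
#' noise. The same peaks appear in both spectrum kinds, but the
#' JRES projection uses narrow linewidths with relatively more noise and the
#' CPMG spectrum uses broadened linewidths with less noise, emulating the
#' resolution / signal-to-noise trade-off between the two experiments.
#'
#' @param signatures Signature tibble (see [example_signatures()]).
#' @param concentrations Samples x metabolites numeric matrix (non-negative),
#'   with metabolite column names matching the signatures.
#' @param ppm ppm axis (strictly monotone); default a 0.5-4.5 ppm grid at
#'   1e-3 ppm resolution.
#' @param jres_fwhm,cpmg_fwhm Linewidths (ppm) of the two spectrum kinds.
#' @param noise_sd_jres,noise_sd_cpmg Additive noise standard deviations, in
#'   the intensity units of a unit-concentration peak.
#' @param baseline Length-2 vector `c(intercept, slope)` of the linear
#'   baseline added to the CPMG spectrum (the resolved JRES projection is
#'   simulated baseline-free).
#' @param seed Optional integer seed.
#' @return An object of class `spectrum_set`: list with `ppm`, intensity
#'   matrices `cpmg` and `jres` (samples x points), the `signatures` and the
#'   generating `concentrations`.
#' @export
simulate_spectra <- function(signatures, concentrations,
                             ppm = seq(0.5, 4.5, by = 1e-3),
                             jres_fwhm = 0.0035, cpmg_fwhm = 0.012,
                             noise_sd_jres = 0.02, noise_sd_cpmg = 0.01,
                             baseline = c(0, 0), seed = NULL) {
  validate_signatures(signatures)
  concentrations <- as.matrix(concentrations)
  if (any(concentrations < 0)) {
    abort("concentrations must be non-negative.",
          class = "mqtl_invalid_argument")
  }
  mets <- unique(signatures$metabolite)
  if (!all(mets %in% colnames(concentrations))) {
    abort("concentration columns must cover all signature metabolites.",
          class = "mqtl_invalid_argument")
  }
  n <- nrow(concentrations)
  with_seed_if(seed, {
    # per-metabolite unit-concentration profiles for each kind
    unit_prof <- function(w) {
      vapply(mets, function(m) {
        pk <- signatures[signatures$metabolite == m, ]
        sum_peaks(ppm, tibble::tibble(center = pk$center, fwhm = w,
                                      amplitude = pk$rel_amplitude,
                                      eta = pk$eta))
      }, numeric(length(ppm)))
    }
    prof_j <- unit_prof(jres_fwhm)   # points x metabolites
    prof_c <- unit_prof(cpmg_fwhm)
    conc <- concentrations[, mets, drop = FALSE]
    base <- baseline[1] + baseline[2] * ppm
    jres <- conc %*% t(prof_j) +
      matrix(rnorm(n * length(ppm), 0, noise_sd_jres), n)
    cpmg <- conc %*% t(prof_c) +
      matrix(base, n, length(ppm), byrow = TRUE) +
      matrix(rnorm(n * length(ppm), 0, noise_sd_cpmg), n)
    rownames(jres) <- rownames(cpmg) <- rownames(concentrations) %||%
      sprintf("S%03d", seq_len(n))
    structure(list(ppm = ppm, cpmg = cpmg, jres = jres,
                   signatures = signatures, concentrations = conc),
              class = "spectrum_set")
  })
}

#' @exportS3Method base::print
print.spectrum_set <- function(x, ...) {
  cat("<spectrum_set> ", nrow(x$cpmg), " samples, ", length(x$ppm),
      " points, ", length(unique(x$signatures$metabolite)),
      " metabolites\n", sep = "")
  invisible(x)
}

#' Extract one spectrum from a set as a tibble
#'
#' @param set A `spectrum_set`.
#' @param sample Sample id or index.
#' @param kind `"cpmg"` or `"jres"`.
#' @return A spectrum tibble with columns `ppm`, `intensity` and attribute
#'   `kind`.
#' @export
get_spectrum <- function(set, sample = 1, kind = c("jres", "cpmg")) {
  kind <- match.arg(kind)
  m <- set[[kind]]
  s <- tibble::tibble(ppm = set$ppm, intensity = m[sample, ])
  attr(s, "kind") <- kind
  s
}

#' Mean spectrum across samples
#'
#' Averaging spectra boosts signal-to-noise for deconvoluting a batch-level
#' peak basis.
#'
#' @inheritParams get_spectrum
#' @return A spectrum tibble.
#' @export
mean_spectrum <- function(set, kind = c("jres", "cpmg")) {
  kind <- match.arg(kind)
  s <- tibble::tibble(ppm = set$ppm, intensity = colMeans(set[[kind]]))
  attr(s, "kind") <- kind
  s
}

#' Spectrum TSV input/output
#'
#' Two-column tab-separated files (`ppm`, `intensity`). Spectra are written
#' with ppm descending (NMR display convention) and stored ascending
#' internally.
#'
#' @param s Spectrum tibble (`ppm`, `intensity`).
#' @param path File path.
#' @return `write_spectrum_tsv()` returns `path` invisibly;
#'   `read_spectrum_tsv()` a spectrum tibble with ascending ppm.
#' @export
write_spectrum_tsv <- function(s, path) {
  readr::write_tsv(s[order(s$ppm, decreasing = TRUE), c("ppm", "intensity")],
                   path)
  invisible(path)
}

#' @rdname write_spectrum_tsv
#' @export
read_spectrum_tsv <- function(path) {
  s <- readr::read_tsv(path, col_types = "dd", progress = FALSE)
  s <- s[order(s$ppm), ]
  validate_spectrum(s)
  s
}

# basic Spectrum invariants: strictly monotone axis, finite intensities
validate_spectrum <- function(s) {
  if (nrow(s) == 0) {
    abort("empty spectrum.", class = "mqtl_invalid_argument")
  }
  d <- diff(s$ppm)
  if (!(all(d > 0) || all(d < 0)) || any(!is.finite(s$intensity))) {
    abort("spectrum axis must be strictly monotone with finite intensities.",
          class = "mqtl_invalid_argument")
  }
  invisible(s)
}
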