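#' Pseudo-Voigt (mixed Gauss-Lorentz) lineshape
#'
#' `A * (eta * L(x) + (1 - eta) * G(x))` where the Lorentzian `L` and
#' Gaussian `G` are unit height at the center `x0` and share the same full
#' width at half maximum `fwhm`, so the profile has height `A` at `x0` and
#' height `A / 2` at `x0 +/- fwhm / 2` for any mixing fraction `eta`.
#'
#' @param x Evaluation points (ppm), vectorized.
#' @param center Peak center x0 (ppm).
#' @param fwhm Full width at half maximum (ppm), > 0.
#' @param amplitude Peak height A, >= 0.
#' @param eta Lorentzian fraction in \[0, 1\].
#' @return Intensity vector, same length as `x`.
#' @export
#' @examples
#' pseudo_voigt(c(3.0, 3.005), center = 3.0, fwhm = 0.01, amplitude = 2,
#'              eta = 0.3)  # 2 and 1
pseudo_voigt <- function(x, center, fwhm, amplitude, eta = 0.5) {
  if (!is.finite(fwhm) || fwhm <= 0) {
    abort("`fwhm` must be positive.", class = "mqtl_invalid_argument")
  }
  if (amplitude < 0 || eta < 0 || eta > 1) {
    abort("need amplitude >= 0 and eta in [0, 1].",
          class = "mqtl_invalid_argument")
  }
  u <- (x - center) / fwhm
  lorentz <- 1 / (1 + 4 * u^2)
  gauss <- exp(-4 * log(2) * u^2)
  amplitude * (eta * lorentz + (1 - eta) * gauss)
}

#' Analytic area of a pseudo-Voigt peak
#'
#' `A * w * (eta * pi / 2 + (1 - eta) * sqrt(pi / log(2)) / 2)`: the sum of
#' the unit-height Lorentzian area `pi * w / 2` and Gaussian area
#' `w / 2 * sqrt(pi / ln 2)` weighted by the mixing fraction.
#'
#' @inheritParams pseudo_voigt
#' @return Peak area (intensity x ppm).
#' @export
pseudo_voigt_area <- function(fwhm, amplitude, eta = 0.5) {
  amplitude * fwhm * (eta * pi / 2 + (1 - eta) * 0.5 * sqrt(pi / log(2)))
}

# Sum of pseudo-Voigt peaks given a peaks tibble (center, fwhm, amplitude,
# eta) on axis x.
sum_peaks <- function(x, peaks) {
  y <- numeric(length(x))
  for (i in seq_len(nrow(peaks))) {
    y <- y + pseudo_voigt(x, peaks$center[i], peaks$fwhm[i],
                          peaks$amplitude[i], peaks$eta[i])
  }
  y
}
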