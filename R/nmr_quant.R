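#' Detect candidate peaks in a resolved spectrum
#'
#' Finds local maxima whose prominence exceeds `min_prominence` times the
#' maximum intensity and seeds a pseudo-Voigt model for each: the center at
#' the maximum, the width from the half-maximum crossings, the amplitude at
#' the maximum and a neutral Lorentzian fraction of 0.5.
#'
#' @param s Spectrum tibble (`ppm`, `intensity`), typically a JRES
#'   projection.
#' @param min_prominence Prominence threshold as a fraction of the maximum
#'   intensity.
#' @param smooth Width (points, made odd) of the moving-average filter
#'   applied before maximum detection; suppresses spurious noise maxima.
#'   The fitted parameters are refined later by [deconvolute()], so the
#'   small smoothing bias does not propagate.
#' @return A peaks tibble (`center`, `fwhm`, `amplitude`, `eta`), ordered by
#'   center.
#' @export
detect_peaks <- function(s, min_prominence = 0.05, smooth = 7) {
  validate_spectrum(s)
  s <- s[order(s$ppm), ]
  y_raw <- s$intensity; x <- s$ppm
  smooth <- max(1L, as.integer(smooth))
  if (smooth %% 2L == 0L) smooth <- smooth + 1L
  y <- if (smooth > 1 && length(y_raw) > smooth) {
    ys <- as.numeric(stats::filter(y_raw, rep(1 / smooth, smooth)))
    ys[is.na(ys)] <- y_raw[is.na(ys)]
    ys
  } else y_raw
  thr <- min_prominence * max(y)
  pk <- pracma::findpeaks(y, minpeakheight = thr, zero = "0")
  if (is.null(pk)) {
    return(tibble::tibble(center = numeric(0), fwhm = numeric(0),
                          amplitude = numeric(0), eta = numeric(0)))
  }
  # prominence relative to the higher of the two flanking valleys
  keep <- apply(pk, 1, function(row) {
    h <- row[1]
    valley <- max(y[row[3]], y[row[4]])
    (h - valley) >= thr
  })
  pk <- pk[keep, , drop = FALSE]
  if (nrow(pk) == 0) {
    return(tibble::tibble(center = numeric(0), fwhm = numeric(0),
                          amplitude = numeric(0), eta = numeric(0)))
  }
  step <- median(diff(x))
  peaks <- purrr::map_dfr(seq_len(nrow(pk)), function(i) {
    ip <- pk[i, 2]; h <- pk[i, 1]
    half <- h / 2
    il <- ip
    while (il > 1 && y[il] > half) il <- il - 1L
    ir <- ip
    while (ir < length(y) && y[ir] > half) ir <- ir + 1L
    wl <- x[ip] - x[il]; wr <- x[ir] - x[ip]
    # if one side never crossed (overlap/edge) mirror the other side
    if (il == 1 && y[il] > half) wl <- wr
    if (ir == length(y) && y[ir] > half) wr <- wl
    w <- max(wl + wr, 2 * step)
    tibble::tibble(center = x[ip], fwhm = w, amplitude = h, eta = 0.5)
  })
  dplyr::arrange(peaks, .data$center)
}

# split the axis into fitting windows at low-signal gaps; returns an integer
# window id per peak plus point ranges per window
fit_windows <- function(x, y, peaks, gap_frac = 0.02, pad = 3L) {
  thr <- gap_frac * max(y)
  hot <- y > thr
  # pad active regions so window edges sit in quiet baseline
  r <- rle(hot)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  act <- which(r$values)
  if (length(act) == 0) {
    return(list(peak_window = rep(1L, nrow(peaks)),
                ranges = list(c(1L, length(x)))))
  }
  lo <- pmax(starts[act] - pad, 1L)
  hi <- pmin(ends[act] + pad, length(x))
  # merge overlapping padded regions
  merged <- list(); cur <- c(lo[1], hi[1])
  for (i in seq_along(lo)[-1]) {
    if (lo[i] <= cur[2] + 1L) cur[2] <- max(cur[2], hi[i])
    else { merged[[length(merged) + 1L]] <- cur; cur <- c(lo[i], hi[i]) }
  }
  merged[[length(merged) + 1L]] <- cur
  pw <- vapply(peaks$center, function(cc) {
    hit <- which(vapply(merged, function(rg)
      cc >= x[rg[1]] && cc <= x[rg[2]], logical(1)))
    if (length(hit)) hit[1] else which.min(vapply(merged, function(rg)
      min(abs(cc - x[rg])), numeric(1)))
  }, integer(1))
  list(peak_window = pw, ranges = merged)
}

# Fit one spectral window: nonlinear parameters per peak are
# (center, log fwhm, eta), searched by restarted Nelder-Mead with
# block-coordinate sweeps; amplitudes are profiled out by linear least
# squares at every evaluation (variable projection), which removes the
# worst-conditioned directions from the simplex search.
fit_window <- function(xi, yi, pk, o) {
  np <- nrow(pk)
  xlo <- xi[1]; xhi <- xi[length(xi)]
  step <- median(diff(xi))
  pscale <- sum(yi^2) + .Machine$double.eps
  lw_lo <- log(step); lw_hi <- log(xhi - xlo)
  l4 <- 4 * log(2)
  shapes_at <- function(m) {
    S <- matrix(0, length(xi), np)
    for (k in seq_len(np)) {
      u <- (xi - m[1, k]) / exp(m[2, k])
      eta <- pmin(pmax(m[3, k], 0), 1)
      S[, k] <- eta / (1 + 4 * u^2) + (1 - eta) * exp(-l4 * u^2)
    }
    S
  }
  amps_for <- function(m) {
    S <- shapes_at(m)
    a <- tryCatch(qr.solve(S, yi), error = function(e) rep(0, np))
    list(S = S, a = a)
  }
  ymax <- max(abs(yi)) + .Machine$double.eps
  obj <- function(par) {
    m <- matrix(par, nrow = 3)
    # soft penalties keep centers inside the window, widths between the
    # grid step and the window span, and eta near [0, 1]
    pen <- sum(pmax(xlo - m[1, ], 0)^2 + pmax(m[1, ] - xhi, 0)^2) /
      (xhi - xlo)^2 +
      sum(pmax(lw_lo - m[2, ], 0)^2 + pmax(m[2, ] - lw_hi, 0)^2) +
      sum(pmax(-m[3, ], 0)^2 + pmax(m[3, ] - 1, 0)^2)
    sa <- amps_for(m)
    # discourage negative profiled amplitudes: two coincident peaks with
    # huge cancelling coefficients can otherwise shave the residual
    pen <- pen + sum(pmax(-sa$a, 0)^2) / ymax^2
    sum((yi - sa$S %*% sa$a)^2) + 10 * pscale * pen
  }
  # overlap-aware initial widths: a half-maximum estimate inflated by a
  # neighbour cannot exceed the distance to that neighbour
  if (np > 1) {
    dmin <- vapply(seq_len(np), function(i)
      min(abs(pk$center[i] - pk$center[-i])), numeric(1))
    pk$fwhm <- pmin(pk$fwhm, pmax(0.8 * dmin, 2 * step))
  }
  par <- as.vector(rbind(pk$center, log(pk$fwhm), pk$eta))
  f0 <- obj(par)
  best <- list(par = par, value = f0)
  # simplex step sizes matched to each parameter's natural scale
  pars_one <- c(max(median(pk$fwhm) / 2, 4 * step), 0.3, 0.2)
  parscale <- rep(pars_one, np)
  ok <- FALSE
  for (r in seq_len(o$max_restarts)) {
    # block-coordinate pass: a 3-parameter simplex per peak is far more
    # reliable than one high-dimensional simplex when peaks overlap
    if (np > 1) {
      for (sweep in 1:2) {
        for (k in seq_len(np)) {
          sel <- (k - 1L) * 3L + 1:3
          objk <- function(pk3) {
            p2 <- best$par; p2[sel] <- pk3
            obj(p2)
          }
          fk <- optim(best$par[sel], objk, method = "Nelder-Mead",
                      control = list(reltol = o$reltol,
                                     maxit = o$maxit_per_dim * 3,
                                     parscale = pars_one))
          if (fk$value < best$value) {
            best$par[sel] <- fk$par
            best$value <- fk$value
          }
        }
      }
    }
    # joint simplex over all nonlinear peak parameters
    fit <- optim(best$par, obj, method = "Nelder-Mead",
                 control = list(reltol = o$reltol,
                                maxit = o$maxit_per_dim * length(par),
                                parscale = parscale))
    improved <- fit$value < best$value * (1 - 1e-3)
    if (fit$value < best$value) best <- fit[c("par", "value")]
    if (best$value < o$tol_obj * pscale ||
        (fit$convergence == 0 && !improved)) { ok <- TRUE; break }
  }
  mbest <- matrix(best$par, nrow = 3)
  sa <- amps_for(mbest)
  peaks <- tibble::tibble(center = mbest[1, ], fwhm = exp(mbest[2, ]),
                          amplitude = as.numeric(sa$a),
                          eta = pmin(pmax(mbest[3, ], 0), 1))
  list(peaks = peaks, value = best$value, ok = ok, rss_init = f0,
       model = as.vector(sa$S %*% sa$a))
}


#' Deconvolute a spectrum into pseudo-Voigt peaks
#'
#' Minimizes the sum of squared residuals between the spectrum and the sum
#' of mixed Gauss-Lorentz peaks over all peak parameters with the
#' Nelder-Mead simplex (standard coefficients: reflection 1, expansion 2,
#' contraction 0.5, shrink 0.5). The spectrum is split at low-signal gaps
#' into independent windows so each simplex handles a modest parameter
#' dimension; within a window the simplex is restarted from its own optimum
#' until the objective stops improving. The returned residual norm can never
#' exceed the residual at the initial parameters, because the simplex always
#' reports its best evaluated vertex.
#'
#' @param s Spectrum tibble (`ppm`, `intensity`).
#' @param init Initial peaks tibble, e.g. from [detect_peaks()].
#' @param opts List of options: `reltol` (simplex relative convergence
#'   tolerance, default 1e-10), `maxit_per_dim` (iteration cap per
#'   parameter, default 200), `max_restarts` (default 20), `tol_obj`
#'   (declare convergence when the residual drops below this fraction of
#'   the spectrum's total power, default 1e-11), `gap_frac`
#'   (window-splitting signal threshold as fraction of max, default 0.02).
#' @return A peaks tibble (`center`, `fwhm`, `amplitude`, `eta`, `window`)
#'   with attributes `rss` (residual sum of squares), `rss_init`,
#'   `converged` (all windows converged within the iteration cap) and
#'   `windows`.
#' @export
deconvolute <- function(s, init, opts = list()) {
  validate_spectrum(s)
  if (is.null(init) || nrow(init) == 0) {
    abort("need at least one initial peak.", class = "mqtl_invalid_argument")
  }
  o <- utils::modifyList(list(reltol = 1e-10, maxit_per_dim = 200,
                              max_restarts = 20, tol_obj = 1e-11,
                              gap_frac = 0.02), opts)
  s <- s[order(s$ppm), ]
  x <- s$ppm; y <- s$intensity
  win <- fit_windows(x, y, init, gap_frac = o$gap_frac)
  fitted <- vector("list", length(win$ranges))
  converged <- TRUE
  rss_init_tot <- 0; rss_tot <- 0
  noise_sd <- mad(diff(y)) / sqrt(2)
  for (w in seq_along(win$ranges)) {
    pk <- init[win$peak_window == w, , drop = FALSE]
    if (nrow(pk) == 0) next
    rg <- win$ranges[[w]]
    xi <- x[rg[1]:rg[2]]; yi <- y[rg[1]:rg[2]]
    res1 <- fit_window(xi, yi, pk, o)
    rss_init_tot <- rss_init_tot + res1$rss_init
    # residual-driven peak insertion: an unresolved shoulder that the
    # detector merged into a neighbour leaves a localized residual well
    # above the noise floor, or a window residual far above the expected
    # noise power
    for (add in seq_len(o$max_add %||% 2L)) {
      resid <- yi - res1$model
      thr_add <- max(6 * noise_sd, 0.03 * max(yi))
      rss_floor <- 3 * length(yi) * noise_sd^2 + 1e-4 * max(yi)^2
      if (max(resid) <= thr_add && res1$value <= rss_floor) break
      imax <- which.max(resid)
      pk2 <- res1$peaks[c("center", "fwhm", "amplitude", "eta")]
      pk2 <- dplyr::bind_rows(pk2, tibble::tibble(
        center = xi[imax], fwhm = median(res1$peaks$fwhm),
        amplitude = resid[imax], eta = 0.5))
      cand <- fit_window(xi, yi, pk2, o)
      if (cand$value < res1$value) res1 <- cand else break
    }
    converged <- converged && res1$ok
    rss_tot <- rss_tot + res1$value
    out <- res1$peaks
    out$window <- w
    fitted[[w]] <- out
  }
  res <- dplyr::arrange(dplyr::bind_rows(fitted), .data$center)
  attr(res, "rss") <- rss_tot
  attr(res, "rss_init") <- rss_init_tot
  attr(res, "converged") <- converged
  attr(res, "windows") <- win$ranges
  res
}

#' Quantify peak intensities from a convoluted CPMG spectrum
#'
#' Fits the CPMG spectrum as a linear combination of the JRES-derived peak
#' shapes, re-broadened by a single multiplicative width factor, plus a
#' polynomial baseline: `c(x) ~ sum_k a_k * shape_k(x) + baseline`.
#' Coefficients are non-negative by default (concentrations cannot be
#' negative), via non-negative least squares with the baseline columns left
#' unconstrained; plain least squares is available with `nonneg = FALSE`.
#'
#' @param cpmg CPMG spectrum tibble on the same ppm axis as the basis fit.
#' @param basis Fitted peaks tibble from [deconvolute()] (JRES projection).
#' @param width_scale Multiplicative broadening factor applied to the basis
#'   widths; if `NULL`, estimated by 1-D minimization of the residual (see
#'   [estimate_width_scale()]).
#' @param baseline_degree Degree of the polynomial baseline (0 = constant,
#'   1 = linear; negative disables the baseline term).
#' @param nonneg Constrain peak coefficients to be non-negative.
#' @return A tibble with one row per basis peak: `center`, `fwhm`, `eta`,
#'   `intensity` (the fitted coefficient a_k); attributes `baseline`
#'   (polynomial coefficients), `width_scale` and `rss`.
#' @export
quantify_cpmg <- function(cpmg, basis, width_scale = NULL,
                          baseline_degree = 1, nonneg = TRUE) {
  validate_spectrum(cpmg)
  cpmg <- cpmg[order(cpmg$ppm), ]
  if (is.null(width_scale)) {
    width_scale <- estimate_width_scale(cpmg, basis,
                                        baseline_degree = baseline_degree)
  }
  x <- cpmg$ppm; y <- cpmg$intensity
  S <- cpmg_design(x, basis, width_scale)
  nb <- if (baseline_degree >= 0) baseline_degree + 1L else 0L
  B <- NULL
  if (nb > 0) {
    B <- matrix(1, length(x), 1)
    if (baseline_degree >= 1) {
      for (dg in seq_len(baseline_degree)) B <- cbind(B, x^dg)
    }
  }
  D <- cbind(S, B)
  if (qr(D)$rank < ncol(D)) {
    abort("degenerate design: duplicate or collinear peak shapes.",
          class = "mqtl_degenerate_design")
  }
  k <- ncol(S)
  if (nonneg) {
    # free baseline columns entered with both signs stay unconstrained
    Dn <- cbind(S, B, if (!is.null(B)) -B)
    fit <- pracma::lsqnonneg(Dn, y)
    a <- fit$x[seq_len(k)]
    bcoef <- if (nb > 0) fit$x[k + seq_len(nb)] - fit$x[k + nb + seq_len(nb)]
    resid <- y - Dn %*% fit$x
  } else {
    cf <- qr.solve(D, y)
    a <- cf[seq_len(k)]
    bcoef <- if (nb > 0) cf[k + seq_len(nb)]
    resid <- y - D %*% cf
  }
  out <- tibble::tibble(center = basis$center,
                        fwhm = basis$fwhm * width_scale,
                        eta = basis$eta, intensity = as.numeric(a))
  attr(out, "baseline") <- if (nb > 0) as.numeric(bcoef)
  attr(out, "width_scale") <- width_scale
  attr(out, "rss") <- sum(resid^2)
  out
}

# unit-amplitude re-broadened shape columns
cpmg_design <- function(x, basis, width_scale) {
  vapply(seq_len(nrow(basis)), function(k) {
    pseudo_voigt(x, basis$center[k], basis$fwhm[k] * width_scale, 1,
                 basis$eta[k])
  }, numeric(length(x)))
}

#' Estimate the CPMG re-broadening factor
#'
#' The JRES projection resolves peaks at narrower linewidth than the CPMG
#' spectrum; a single multiplicative width factor per batch links the two.
#' The factor is estimated by 1-D minimization of the (pooled) ordinary
#' least-squares residual of the CPMG fit over the factor.
#'
#' @param cpmg One CPMG spectrum tibble, or a list of them to pool.
#' @param basis Fitted JRES peaks tibble.
#' @param interval Search interval for the factor.
#' @param baseline_degree Baseline polynomial degree used during the search.
#' @return The estimated width factor (numeric scalar).
#' @export
estimate_width_scale <- function(cpmg, basis, interval = c(1, 8),
                                 baseline_degree = 1) {
  specs <- if (is.data.frame(cpmg)) list(cpmg) else cpmg
  rss_at <- function(ws) {
    sum(vapply(specs, function(s) {
      s <- s[order(s$ppm), ]
      D <- cpmg_design(s$ppm, basis, ws)
      if (baseline_degree >= 0) {
        D <- cbind(D, 1)
        if (baseline_degree > 0) D <- cbind(D, s$ppm)
      }
      f <- lm.fit(D, s$intensity)
      sum(f$residuals^2)
    }, numeric(1)))
  }
  optimize(rss_at, interval)$minimum
}

#' Quantify a batch of CPMG spectra against one peak basis
#'
#' Estimates the width factor once from the batch, then runs
#' [quantify_cpmg()] on every sample.
#'
#' @param set A `spectrum_set`.
#' @param basis Fitted peaks tibble (from the JRES projection).
#' @param n_scale_samples Number of spectra pooled for the width-factor
#'   estimate.
#' @param ... Passed to [quantify_cpmg()].
#' @return A `peak_intensity` object: list with `intensity` (samples x
#'   peaks matrix) and `peaks` (the basis metadata).
#' @export
quantify_samples <- function(set, basis, n_scale_samples = 5, ...) {
  n <- nrow(set$cpmg)
  sub <- lapply(seq_len(min(n_scale_samples, n)),
                function(i) get_spectrum(set, i, "cpmg"))
  ws <- estimate_width_scale(sub, basis)
  res <- vapply(seq_len(n), function(i) {
    quantify_cpmg(get_spectrum(set, i, "cpmg"), basis, width_scale = ws,
                  ...)$intensity
  }, numeric(nrow(basis)))
  M <- t(res)
  rownames(M) <- rownames(set$cpmg)
  colnames(M) <- sprintf("peak%03d", seq_len(nrow(basis)))
  structure(list(intensity = M, peaks = basis, width_scale = ws),
            class = "peak_intensity")
}

#' @exportS3Method base::print
print.peak_intensity <- function(x, ...) {
  cat("<peak_intensity> ", nrow(x$intensity), " samples x ",
      ncol(x$intensity), " peaks\n", sep = "")
  invisible(x)
}

#' Group deconvoluted peaks into candidate metabolites
#'
#' Peaks belonging to one metabolite rise and fall together across samples;
#' single-linkage clustering of the across-sample Pearson correlation at
#' threshold `r_threshold` groups them. A threshold above 1 leaves every
#' peak in its own group.
#'
#' @param P A `peak_intensity` object (or bare samples x peaks matrix).
#' @param r_threshold Correlation threshold for joining peaks.
#' @return A tibble with `peak`, `center` (if available) and `group` labels
#'   (`"M01"`, `"M02"`, ... ordered by first peak center).
#' @export
group_peaks <- function(P, r_threshold = 0.8) {
  M <- if (inherits(P, "peak_intensity")) P$intensity else as.matrix(P)
  if (nrow(M) < 3) {
    abort("need at least 3 samples to correlate peaks.",
          class = "mqtl_insufficient_data")
  }
  k <- ncol(M)
  if (r_threshold > 1) {
    grp <- seq_len(k)
  } else {
    r <- suppressWarnings(cor(M, use = "pairwise.complete.obs"))
    r[!is.finite(r)] <- 0
    d <- stats::as.dist(1 - r)
    hc <- stats::hclust(d, method = "single")
    grp <- stats::cutree(hc, h = 1 - r_threshold)
  }
  centers <- if (inherits(P, "peak_intensity")) P$peaks$center else
    rep(NA_real_, k)
  out <- tibble::tibble(peak = colnames(M) %||% sprintf("peak%03d", 1:k),
                        center = centers, group = grp)
  # stable labels ordered by the leftmost member peak
  first <- tapply(seq_len(k), grp, min)
  relabel <- rank(first)
  out$group <- sprintf("M%02d", relabel[as.character(out$group)])
  out
}

#' Sum grouped peak intensities into metabolite intensities
#'
#' @param P A `peak_intensity` object.
#' @param groups Peak grouping from [group_peaks()].
#' @return A tibble with one row per sample (`id` column) and one column per
#'   metabolite group.
#' @export
metabolite_intensities <- function(P, groups) {
  M <- P$intensity
  out <- sapply(split(groups$peak, groups$group), function(pk) {
    rowSums(M[, pk, drop = FALSE])
  })
  tibble::as_tibble(out, rownames = "id")
}

#' Quality control for a 1D spectrum
#'
#' Flags spectra whose signal-to-noise ratio (maximum baseline-corrected
#' signal over a robust noise estimate from first differences) falls below
#' `min_snr`, or whose fitted linear baseline drifts across the axis by more
#' than `max_baseline_drift` times the maximum intensity. These criteria are
#' an explicit stand-in for an instrument-specific QC protocol: the upstream
#' procedure this emulates is not publicly specified.
#'
#' @param s Spectrum tibble.
#' @param min_snr Minimum acceptable signal-to-noise ratio.
#' @param max_baseline_drift Maximum acceptable baseline drift across the
#'   axis, as a fraction of the maximum intensity.
#' @return A one-row tibble: `pass`, `snr`, `baseline_drift`, `reasons`
#'   (comma-separated failure reasons, `""` when passing).
#' @export
qc_spectrum <- function(s, min_snr = 10, max_baseline_drift = 0.2) {
  validate_spectrum(s)
  s <- s[order(s$ppm), ]
  y <- s$intensity; x <- s$ppm
  noise_sd <- mad(diff(y)) / sqrt(2)
  bl <- lm.fit(cbind(1, x), y)
  drift <- abs(coef(bl)[2]) * diff(range(x))
  signal <- max(y - cbind(1, x) %*% coef(bl))
  snr <- if (noise_sd > 0) signal / noise_sd else Inf
  drift_frac <- drift / max(max(abs(y)), .Machine$double.eps)
  reasons <- c(if (snr < min_snr) "snr",
               if (drift_frac > max_baseline_drift) "baseline")
  tibble::tibble(pass = length(reasons) == 0, snr = snr,
                 baseline_drift = drift_frac,
                 reasons = paste(reasons, collapse = ","))
}
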