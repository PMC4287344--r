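#' Eigendecomposition of the additive relationship matrix
#'
#' The polygenic REML fit and the mixed-model score test both work in the
#' eigenbasis of `A = 2 * Phi` (the additive genetic relationship matrix).
#' Decomposing once and passing the result to [reml_fit()] /
#' [null_model()] amortizes the O(n^3) cost across the metabolites that
#' share one pedigree.
#'
#' @param K Kinship matrix.
#' @return List with `U` (eigenvectors), `d` (eigenvalues of `2 * K`) and
#'   `ids` (dimnames order).
#' @export
kinship_eigen <- function(K) {
  n <- nrow(K)
  offdiag_max <- max(abs(K[upper.tri(K)]), 0)
  if (offdiag_max == 0) {
    # diagonal kinship (unrelated samples): the eigenbasis is trivial
    return(list(U = diag(n), d = pmax(2 * diag(K), 0), ids = rownames(K)))
  }
  ee <- eigen(2 * K, symmetric = TRUE)
  list(U = ee$vectors, d = pmax(ee$values, 0), ids = rownames(K))
}

# Woodbury-based evaluation of generalized least squares under
# R = gam_g * D + gam_c * Zt Zt' + I in the eigenbasis of A.
# Returns quadratic forms, log-determinant pieces and the GLS fit.
reml_eval <- function(gam_g, gam_c, d, yt, Xt, Zt) {
  n <- length(yt); p <- ncol(Xt)
  w <- gam_g * d + 1
  T <- cbind(yt, Xt)
  WT <- T / w
  if (!is.null(Zt) && gam_c > 0) {
    q <- ncol(Zt)
    ZtW <- Zt / w
    C <- diag(1 / gam_c, q) + crossprod(Zt / sqrt(w))
    ch <- tryCatch(chol(C), error = function(e) NULL)
    if (is.null(ch)) return(NULL)
    ZtWT <- crossprod(Zt, WT)
    RinvT <- WT - ZtW %*% backsolve(ch, forwardsolve(t(ch), ZtWT))
    logdetR <- sum(log(w)) + 2 * sum(log(diag(ch))) + q * log(gam_c)
  } else {
    RinvT <- WT
    logdetR <- sum(log(w))
  }
  M <- crossprod(T, RinvT)
  XRX <- M[-1, -1, drop = FALSE]
  XRy <- M[-1, 1]
  yRy <- M[1, 1]
  chX <- tryCatch(chol(XRX), error = function(e) NULL)
  if (is.null(chX)) return(NULL)
  beta <- backsolve(chX, forwardsolve(t(chX), XRy))
  rss <- max(yRy - sum(XRy * beta), 1e-300)
  sigma2e <- rss / (n - p)
  ll <- -0.5 * ((n - p) * log(sigma2e) + logdetR +
                  2 * sum(log(diag(chX))) + (n - p))
  list(ll = ll, beta = beta, sigma2e = sigma2e, logdetR = logdetR,
       XRX = XRX, RinvT = RinvT, w = w)
}

# Unprofiled restricted log-likelihood at absolute variances
# vc = (sigma2_g, sigma2_c, sigma2_e); used for the numerical Hessian.
reml_ll_abs <- function(vc, d, yt, Xt, Zt) {
  s2g <- vc[1]; s2c <- vc[2]; s2e <- vc[3]
  if (s2e <= 0 || s2g < 0 || s2c < 0) return(-Inf)
  ev <- reml_eval(s2g / s2e, s2c / s2e, d, yt, Xt, Zt)
  if (is.null(ev)) return(-Inf)
  n <- length(yt); p <- ncol(Xt)
  # convert the profiled pieces back to the unprofiled criterion at s2e
  rss_R <- ev$sigma2e * (n - p)
  -0.5 * (n * log(s2e) + ev$logdetR - p * log(s2e) +
            determinant(ev$XRX)$modulus[1] - 0 + rss_R / s2e) -
    0.5 * 0  # constant dropped
}

#' REML fit of the polygenic variance-components model
#'
#' Maximizes the restricted likelihood of
#' `y ~ N(X b, sigma2_g * 2 Phi + sigma2_c * H + sigma2_e * I)` over
#' non-negative variances, where `2 Phi` is the additive relationship matrix
#' and `H` the household (sibship) sharing matrix. The residual scale is
#' profiled out analytically; the remaining variance ratios are searched on
#' the log scale by bounded derivative-free optimization (a nested
#' golden-section/Brent search when the household component is present,
#' with preset starting points probed as a safeguard against a missed
#' basin, refined by Nelder-Mead if a probe wins), with an explicit
#' boundary refit when a component collapses below 1e-6 of the total
#' variance. Fixed effects are estimated by GLS at the optimum.
#'
#' @param y Numeric trait vector (complete cases only).
#' @param X Covariate matrix (intercept added if absent); `NULL` for
#'   intercept only.
#' @param kinship Kinship matrix aligned with `y`.
#' @param household Optional household factor/character vector (length n) or
#'   0/1 design matrix; `NULL` drops the household component.
#' @param eigen_A Optional precomputed [kinship_eigen()] result.
#' @param control List: `reltol` (default 1e-10), `maxit` (default 500),
#'   `starts` (matrix of (h2, c2) starting points).
#' @return Object of class `reml_fit` with elements `varcomp` (named
#'   genetic / household / residual variances), `h2`, `c2`, `se` (delta-
#'   method SEs for all five), `beta` (fixed-effect tibble), `logLik`
#'   (restricted), `converged`, `flags` (identifiability warnings), `n`,
#'   `p`.
#' @export
reml_fit <- function(y, X = NULL, kinship, household = NULL,
                     eigen_A = NULL, control = list()) {
  ctl <- utils::modifyList(
    list(reltol = 1e-9, maxit = 400,
         starts = rbind(c(0.2, 0.05), c(0.5, 0.15), c(0.05, 0.02))),
    control)
  y <- as.numeric(y)
  n <- length(y)
  if (anyNA(y)) abort("`y` must be complete; subset first.",
                      class = "mqtl_invalid_argument")
  X <- if (is.null(X)) matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  else as.matrix(X)
  if (!any(apply(X, 2, function(col) all(col == col[1])))) {
    X <- cbind(`(Intercept)` = 1, X)
  }
  p <- ncol(X)
  if (qr(X)$rank < p) abort("covariate matrix is rank deficient.",
                            class = "mqtl_invalid_argument")
  if (nrow(kinship) != n) abort("kinship dimension mismatch.",
                                class = "mqtl_invalid_argument")
  flags <- character(0)
  ea <- eigen_A %||% kinship_eigen(kinship)
  if (any(ea$d < -1e-8)) abort("kinship matrix is not positive semi-definite.",
                               class = "mqtl_matrix_error")
  U <- ea$U; d <- ea$d
  yt <- as.vector(crossprod(U, y))
  Xt <- crossprod(U, X)
  Z <- NULL
  if (!is.null(household)) {
    Z <- if (is.matrix(household)) household else {
      hh <- factor(household)
      Zm <- matrix(0, n, nlevels(hh))
      Zm[cbind(seq_len(n), as.integer(hh))] <- 1
      Zm
    }
    if (all(colSums(Z) <= 1)) {
      flags <- c(flags, "household_identity_unidentifiable")
      Z <- NULL
    }
  }
  if (sd(d) < 1e-10) flags <- c(flags, "kinship_identity_unidentifiable")
  Zt <- if (!is.null(Z)) crossprod(U, Z)
  use_hh <- !is.null(Zt)

  obj <- function(par) {
    gg <- exp(par[1]); gc <- if (use_hh) exp(par[2]) else 0
    ev <- reml_eval(gg, gc, d, yt, Xt, Zt)
    if (is.null(ev)) return(1e10)
    -ev$ll
  }
  if (use_hh) {
    # nested derivative-free search over the log variance ratios: for each
    # genetic ratio the O(n q^2) pieces are computed once, and the inner
    # search over the household ratio works on q x q matrices only
    n_ <- n; p_ <- p
    T_ <- cbind(yt, Xt)
    q <- ncol(Zt)
    outer_eval <- function(lg) {
      gg <- exp(lg)
      w <- gg * d + 1
      WT <- T_ / w
      TWT <- crossprod(T_, WT)
      M <- crossprod(Zt / sqrt(w))
      ZtWT <- crossprod(Zt, WT)
      sum_log_w <- sum(log(w))
      neg_ll_c <- function(lc) {
        gc_ <- exp(lc)
        C <- M
        diag(C) <- diag(C) + 1 / gc_
        ch <- tryCatch(chol(C), error = function(e) NULL)
        if (is.null(ch)) return(1e10)
        Mq <- TWT - crossprod(ZtWT, backsolve(ch, forwardsolve(t(ch), ZtWT)))
        XRX <- Mq[-1, -1, drop = FALSE]
        chX <- tryCatch(chol(XRX), error = function(e) NULL)
        if (is.null(chX)) return(1e10)
        beta <- backsolve(chX, forwardsolve(t(chX), Mq[-1, 1]))
        rss <- max(Mq[1, 1] - sum(Mq[-1, 1] * beta), 1e-300)
        logdetR <- sum_log_w + 2 * sum(log(diag(ch))) + q * log(gc_)
        0.5 * ((n_ - p_) * log(rss / (n_ - p_)) + logdetR +
                 2 * sum(log(diag(chX))) + (n_ - p_))
      }
      op_c <- optimize(neg_ll_c, c(-16, 6), tol = 1e-5)
      list(value = op_c$objective, lc = op_c$minimum)
    }
    op_g <- optimize(function(lg) outer_eval(lg)$value, c(-16, 6),
                     tol = 1e-6)
    inner <- outer_eval(op_g$minimum)
    best <- list(par = c(op_g$minimum, inner$lc), value = inner$value)
    # guard against a missed basin: probe the preset starting points
    for (s in seq_len(nrow(ctl$starts))) {
      h2s <- ctl$starts[s, 1]; c2s <- ctl$starts[s, 2]
      e2s <- max(1 - h2s - c2s, 0.05)
      pr <- log(c(h2s / e2s, c2s / e2s))
      if (obj(pr) < best$value - 1e-6) {
        fit2 <- optim(pr, obj, method = "Nelder-Mead",
                      control = list(reltol = ctl$reltol,
                                     maxit = ctl$maxit))
        if (fit2$value < best$value) best <- fit2[c("par", "value")]
      }
    }
    conv <- TRUE
  } else {
    best <- NULL
    op <- optimize(function(u) obj(u), c(-16, 10), tol = 1e-9)
    best <- list(par = op$minimum, value = op$objective)
    conv <- TRUE
  }
  gam_g <- exp(best$par[1])
  gam_c <- if (use_hh) exp(best$par[2]) else 0
  # boundary refits: collapse components below 1e-6 of total variance
  tot <- gam_g + gam_c + 1
  if (gam_g / tot < 1e-6 || (use_hh && gam_c / tot < 1e-6)) {
    drop_g <- gam_g / tot < 1e-6
    drop_c <- use_hh && gam_c / tot < 1e-6
    if (drop_g && (!use_hh || drop_c)) {
      gam_g <- 0; gam_c <- 0
    } else if (drop_g) {
      op <- optimize(function(u) {
        ev <- reml_eval(0, exp(u), d, yt, Xt, Zt)
        if (is.null(ev)) 1e10 else -ev$ll
      }, c(-16, 10), tol = 1e-9)
      gam_g <- 0; gam_c <- exp(op$minimum)
      if (gam_c / (gam_c + 1) < 1e-6) gam_c <- 0
    } else if (drop_c) {
      op <- optimize(function(u) {
        ev <- reml_eval(exp(u), 0, d, yt, Xt, NULL)
        if (is.null(ev)) 1e10 else -ev$ll
      }, c(-16, 10), tol = 1e-9)
      gam_c <- 0; gam_g <- exp(op$minimum)
      if (gam_g / (gam_g + 1) < 1e-6) gam_g <- 0
    }
  }
  ev <- reml_eval(gam_g, gam_c, d, yt, Xt, if (gam_c > 0) Zt else NULL)
  s2e <- ev$sigma2e
  vc <- c(genetic = gam_g * s2e, household = gam_c * s2e, residual = s2e)
  totv <- sum(vc)
  h2 <- vc[["genetic"]] / totv
  c2 <- vc[["household"]] / totv
  # SEs from the numerical Hessian of the unprofiled restricted likelihood
  se <- rep(NA_real_, 5)
  names(se) <- c("genetic", "household", "residual", "h2", "c2")
  hess <- tryCatch({
    free <- c(TRUE, use_hh, TRUE)
    f <- function(v) {
      vfull <- c(0, 0, 0)
      vfull[free] <- v
      reml_ll_abs(vfull, d, yt, Xt, if (use_hh) Zt else NULL)
    }
    v0 <- vc[free]
    hstep <- pmax(abs(v0) * 1e-3, totv * 1e-5)
    k <- length(v0)
    H <- matrix(NA_real_, k, k)
    for (i in seq_len(k)) for (j in i:k) {
      ei <- ej <- rep(0, k); ei[i] <- hstep[i]; ej[j] <- hstep[j]
      H[i, j] <- H[j, i] <-
        (f(v0 + ei + ej) - f(v0 + ei - ej) - f(v0 - ei + ej) +
           f(v0 - ei - ej)) / (4 * hstep[i] * hstep[j])
    }
    V <- solve(-H)
    diag(V)[diag(V) < 0] <- NA
    sev <- sqrt(diag(V))
    se[c("genetic", "household", "residual")[free]] <- sev
    # delta method for the ratios
    gr_h2 <- c((totv - vc[1]), -vc[1], -vc[1])[free] / totv^2
    se["h2"] <- sqrt(max(crossprod(gr_h2, V %*% gr_h2), 0))
    if (use_hh) {
      gr_c2 <- c(-vc[2], totv - vc[2], -vc[2])[free] / totv^2
      se["c2"] <- sqrt(max(crossprod(gr_c2, V %*% gr_c2), 0))
    }
    TRUE
  }, error = function(e) FALSE)
  beta <- tibble::tibble(term = colnames(X) %||% sprintf("x%d", 1:p),
                         estimate = as.numeric(ev$beta))
  structure(list(varcomp = vc, h2 = h2, c2 = c2, se = se, beta = beta,
                 logLik = ev$ll, converged = conv, flags = flags,
                 n = n, p = p, gamma = c(g = gam_g, c = gam_c),
                 used_household = gam_c > 0 || use_hh),
            class = "reml_fit")
}

#' @exportS3Method base::print
print.reml_fit <- function(x, ...) {
  cat("Polygenic REML fit (n = ", x$n, ")\n", sep = "")
  cat(sprintf("  h2 = %.3f (SE %.3f), c2 = %.3f (SE %.3f)\n",
              x$h2, x$se["h2"], x$c2, x$se["c2"]))
  cat("  variances:", paste(sprintf("%s = %.4f", names(x$varcomp),
                                    x$varcomp), collapse = ", "), "\n")
  cat("  restricted logLik =", format(x$logLik), "| converged:",
      x$converged, "\n")
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' Heritability and household-effect fractions from a fit
#'
#' `h2 = sigma2_g / total`, `c2 = sigma2_c / total`.
#'
#' @param v A `reml_fit`.
#' @return Named numeric vector `c(h2 = , c2 = )`.
#' @export
heritability <- function(v) {
  stopifnot(inherits(v, "reml_fit"))
  if (!isTRUE(v$converged)) {
    warning("REML fit did not converge; ratios may be unreliable.")
  }
  tot <- sum(v$varcomp)
  if (tot <= 0) abort("total variance is zero; ratios undefined.",
                      class = "mqtl_undefined_ratio")
  c(h2 = v$varcomp[["genetic"]] / tot,
    c2 = v$varcomp[["household"]] / tot)
}

#' Tidy a polygenic REML fit
#'
#' @param x A `reml_fit`.
#' @param ... Unused.
#' @return Tibble with one row per variance component and derived ratio:
#'   `term`, `estimate`, `std.error`.
#' @export
tidy.reml_fit <- function(x, ...) {
  tibble::tibble(
    term = c("var_genetic", "var_household", "var_residual", "h2", "c2"),
    estimate = c(unname(x$varcomp), x$h2, x$c2),
    std.error = unname(x$se))
}

#' Glance at a polygenic REML fit
#'
#' @param x A `reml_fit`.
#' @param ... Unused.
#' @return One-row tibble: `logLik`, `converged`, `n`, `p`, `flags`.
#' @export
glance.reml_fit <- function(x, ...) {
  tibble::tibble(logLik = x$logLik, converged = x$converged, n = x$n,
                 p = x$p, flags = paste(x$flags, collapse = ";"))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Fit the polygenic model for one trait of a phenotype table
#'
#' Convenience wrapper assembling `y`, covariates (age, sex by default) and
#' the household structure from a phenotype tibble, then calling
#' [reml_fit()].
#'
#' @param data Phenotype tibble with `id`, covariate columns and the trait.
#' @param trait Trait column name.
#' @param covariates Covariate column names (character ones are converted to
#'   0/1 dummies).
#' @param kinship Kinship matrix (dimnames = ids).
#' @param household Use the `household` column as shared-environment
#'   component?
#' @param eigen_A Optional precomputed [kinship_eigen()].
#' @param ... Passed to [reml_fit()].
#' @return A `reml_fit`.
#' @export
fit_polygenic <- function(data, trait = "y", covariates = c("age", "sex"),
                          kinship, household = TRUE, eigen_A = NULL, ...) {
  keep <- !is.na(data[[trait]])
  dd <- data[keep, ]
  X <- covariate_matrix(dd, covariates)
  K <- kinship[dd$id, dd$id]
  if (!all(keep) && !is.null(eigen_A)) eigen_A <- NULL  # subset invalidates
  reml_fit(dd[[trait]], X, K,
           household = if (household) dd$household else NULL,
           eigen_A = eigen_A, ...)
}

# numeric covariate matrix from a tibble; character/factor -> dummies
covariate_matrix <- function(data, covariates) {
  if (length(covariates) == 0) return(NULL)
  cols <- lapply(covariates, function(cv) {
    v <- data[[cv]]
    if (is.numeric(v)) return(setNames(list(v), cv))
    f <- factor(v)
    lv <- levels(f)[-1]
    setNames(lapply(lv, function(l) as.numeric(f == l)),
             paste0(cv, lv))
  })
  cols <- unlist(cols, recursive = FALSE)
  do.call(cbind, cols)
}
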