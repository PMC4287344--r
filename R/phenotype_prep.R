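#' Remove extreme trait values
#'
#' Sets to missing every value more than `k` standard deviations from the
#' mean, with mean and SD computed once over the non-missing values (no
#' re-estimation after removal: iterating would be a different rule). With
#' zero SD (constant vector) the rule is vacuous and nothing is removed.
#'
#' @param x Numeric trait vector (may contain `NA`).
#' @param k SD multiple; default 4.
#' @return `x` with outliers set to `NA`; attribute `n_removed` records the
#'   count.
#' @export
remove_outliers <- function(x, k = 4) {
  obs <- !is.na(x)
  if (sum(obs) < 2) {
    abort("need at least 2 non-missing values.",
          class = "mqtl_insufficient_data")
  }
  m <- mean(x[obs]); s <- sd(x[obs])
  out <- obs & s > 0 & abs(x - m) > k * s
  x[out] <- NA
  attr(x, "n_removed") <- sum(out)
  x
}

#' Rank-transform a trait
#'
#' Replaces non-missing values by their ranks `1..m` (ties get the average
#' rank); missing values stay missing and do not consume ranks.
#'
#' @param x Numeric trait vector.
#' @return Ranked vector of the same length.
#' @export
#' @examples
#' rank_transform(c(3.1, 2.0, NA, 5.5))  # 2 1 NA 3
rank_transform <- function(x) {
  if (all(is.na(x))) {
    abort("need at least 1 non-missing value.",
          class = "mqtl_insufficient_data")
  }
  rank(x, na.last = "keep", ties.method = "average")
}

#' Exclude flagged samples
#'
#' Retains samples with all exclusion flags `FALSE` and reports counts per
#' exclusion reason. Flags may be logical columns of `meta` (named in
#' `flag_cols`) or a separate table with an `id` column; ids unknown to
#' `meta` are an error.
#'
#' @param meta Metadata tibble with an `id` column.
#' @param flags Optional tibble (`id` + logical flag columns).
#' @param flag_cols Names of logical columns in `meta` to use as flags.
#' @return The retained rows of `meta`, with attribute `exclusions`: a
#'   tibble of per-reason counts plus `n_input` / `n_retained`.
#' @export
exclude_samples <- function(meta, flags = NULL, flag_cols = NULL) {
  stopifnot("id" %in% names(meta))
  if (!is.null(flags)) {
    if (!all(flags$id %in% meta$id)) {
      abort("flags reference unknown sample ids.", class = "mqtl_key_error")
    }
    fl <- dplyr::left_join(meta["id"], flags, by = "id")
    fcols <- setdiff(names(fl), "id")
    fm <- as.matrix(fl[fcols])
    fm[is.na(fm)] <- FALSE
  } else {
    fcols <- flag_cols %||% character(0)
    fm <- as.matrix(meta[fcols])
    mode(fm) <- "logical"
  }
  drop <- if (length(fcols)) rowSums(fm, na.rm = TRUE) > 0 else
    rep(FALSE, nrow(meta))
  counts <- tibble::tibble(reason = fcols,
                           n_flagged = if (length(fcols))
                             unname(colSums(fm)) else integer(0))
  out <- meta[!drop, ]
  attr(out, "exclusions") <- list(per_reason = counts,
                                  n_input = nrow(meta),
                                  n_retained = nrow(out))
  out
}

#' Partial correlation of two traits given covariates
#'
#' Pearson correlation of the residuals of `x` and `y` after linear
#' regression on the covariates, with the p-value from the t distribution on
#' `n - n_covariates - 2` degrees of freedom. With no covariates this is the
#' ordinary Pearson correlation test.
#'
#' @param x,y Numeric vectors.
#' @param covariates Optional numeric matrix / data frame of covariates.
#' @return One-row tibble: `estimate`, `statistic`, `p.value`, `n`,
#'   `df`.
#' @export
partial_correlation <- function(x, y, covariates = NULL) {
  C <- if (is.null(covariates)) NULL else as.matrix(covariates)
  q <- if (is.null(C)) 0L else ncol(C)
  cc <- stats::complete.cases(x, y, if (!is.null(C)) C)
  n <- sum(cc)
  if (n < q + 3) {
    abort("insufficient complete cases for partial correlation.",
          class = "mqtl_insufficient_data")
  }
  X <- matrix(1, n, 1)
  if (!is.null(C)) X <- cbind(X, C[cc, , drop = FALSE])
  rx <- lm.fit(X, as.numeric(x[cc]))$residuals
  ry <- lm.fit(X, as.numeric(y[cc]))$residuals
  r <- cor(rx, ry)
  df <- n - q - 2L
  tstat <- r * sqrt(df / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tstat), df)
  tibble::tibble(estimate = r, statistic = tstat, p.value = p, n = n,
                 df = df)
}

#' Prepare metabolite traits for genetic analysis
#'
#' Fixed pipeline, in this order: exclude flagged samples, remove values
#' beyond `k` SD of the mean, rank-transform. The steps applied are recorded
#' in the `history` attribute.
#'
#' @param data Tibble with `id`, trait columns and optional flag columns.
#' @param traits Character vector of trait column names.
#' @param flag_cols Logical exclusion columns (e.g. `"medication"`).
#' @param k Outlier SD multiple.
#' @return The processed tibble (excluded samples dropped, traits
#'   transformed), with attributes `history` and `exclusions`.
#' @export
prepare_traits <- function(data, traits, flag_cols = NULL, k = 4) {
  out <- exclude_samples(data, flag_cols = flag_cols)
  excl <- attr(out, "exclusions")
  for (tr in traits) {
    out[[tr]] <- rank_transform(remove_outliers(out[[tr]], k = k))
  }
  attr(out, "history") <- c(
    sprintf("exclude_samples(%s)", paste(flag_cols, collapse = ",")),
    sprintf("remove_outliers(k=%g)", k), "rank_transform()")
  attr(out, "exclusions") <- excl
  out
}
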