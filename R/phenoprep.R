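#' Log-transform a trait with zero replacement
#'
#' Skewed traits are natural-log transformed; exact zeros (e.g. values below a
#' detection threshold) are first replaced by a stated positive value such as
#' half the detection threshold.
#'
#' @param x Numeric trait vector, or a data frame with a `value` column.
#' @param log Apply the natural log?
#' @param zero_value Replacement for exact zeros; required (and positive) when
#'   `log = TRUE` and zeros are present.
#' @return Transformed vector (or data frame with transformed `value`).
#' @examples
#' transform_trait(c(0, 1, 2.5), log = TRUE, zero_value = 0.002)
#' @export
transform_trait <- function(x, log = FALSE, zero_value = NULL) {
  if (is.data.frame(x)) {
    check_columns(x, "value", "x")
    x$value <- transform_trait(x$value, log = log, zero_value = zero_value)
    return(tibble::as_tibble(x))
  }
  stopifnot(is.numeric(x))
  if (!log) return(x)
  if (any(x == 0, na.rm = TRUE)) {
    if (is.null(zero_value) || zero_value <= 0) {
      abort("Zeros present: `zero_value` must be a positive replacement when `log = TRUE`.")
    }
    x[x == 0] <- zero_value
  }
  neg <- which(x < 0)
  if (length(neg)) {
    abort(sprintf("Cannot log-transform negative values at position(s): %s.",
                  paste(head(neg, 5), collapse = ", ")))
  }
  base::log(x)
}

#' Adjust a trait for covariates and PCs and standardize the residuals
#'
#' Regresses the trait on an intercept, the covariates and the principal
#' component eigenvectors by ordinary least squares, and standardizes the
#' residuals to mean 0 and variance 1. Collinear design columns are dropped
#' with a warning.
#'
#' @param trait Numeric vector, or data frame with `sample_id` and `value`.
#' @param covariates Optional numeric matrix / data frame of covariates
#'   (rows in trait order).
#' @param pcs Optional `pc_result` or eigenvector matrix (rows in trait order,
#'   or named rows matched by `sample_id` when `trait` is a data frame).
#' @return Same shape as `trait` with standardized residual values.
#' @export
adjust_and_standardize <- function(trait, covariates = NULL, pcs = NULL) {
  if (is.data.frame(trait)) {
    check_columns(trait, "value", "trait")
    trait$value <- adjust_and_standardize(
      trait$value, covariates = covariates,
      pcs = align_pcs(pcs, trait[["sample_id"]]))
    return(tibble::as_tibble(trait))
  }
  stopifnot(is.numeric(trait))
  X <- design_matrix(length(trait), covariates, pcs)
  if (length(trait) <= ncol(X)) {
    abort(sprintf("Only %d samples for %d predictors.", length(trait), ncol(X)))
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    warn(sprintf("Dropping %d collinear design column(s).", ncol(X) - qrX$rank))
  }
  res <- qr.resid(qrX, trait)
  s <- sd(res)
  if (!is.finite(s) || s < 1e-12) {
    abort("Residuals are (numerically) constant: the adjusted trait is degenerate.")
  }
  (res - mean(res)) / s
}

design_matrix <- function(n, covariates, pcs) {
  X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  if (!is.null(covariates)) {
    cv <- as.matrix(covariates)
    stopifnot(nrow(cv) == n)
    X <- cbind(X, cv)
  }
  if (!is.null(pcs)) {
    pv <- if (inherits(pcs, "pc_result")) pcs$vectors else as.matrix(pcs)
    stopifnot(nrow(pv) == n)
    X <- cbind(X, pv)
  }
  storage.mode(X) <- "double"
  X
}

align_pcs <- function(pcs, ids) {
  if (is.null(pcs) || is.null(ids)) return(pcs)
  pv <- if (inherits(pcs, "pc_result")) pcs$vectors else as.matrix(pcs)
  if (!is.null(rownames(pv)) && all(ids %in% rownames(pv))) {
    pv[ids, , drop = FALSE]
  } else {
    pv
  }
}

#' Truncate trait outliers at a multiple of the standard deviation
#'
#' Values further than `n_sd` standard deviations from the mean are clamped to
#' the boundary. Mean and SD are those of the input vector, computed once
#' before any clamping (a single pass). Truncation never increases the
#' variance.
#'
#' @param x Numeric vector, or data frame with a `value` column.
#' @param n_sd Number of standard deviations (default 4).
#' @return Same shape as `x`, clamped.
#' @export
truncate_outliers <- function(x, n_sd = 4) {
  if (is.data.frame(x)) {
    check_columns(x, "value", "x")
    x$value <- truncate_outliers(x$value, n_sd = n_sd)
    return(tibble::as_tibble(x))
  }
  stopifnot(is.numeric(x))
  check_scalar_number(n_sd, "n_sd", lower = 1e-12)
  mu <- mean(x, na.rm = TRUE)
  s <- sd(x[!is.na(x)])
  if (!is.finite(s) || s == 0) return(x)
  pmin(pmax(x, mu - n_sd * s), mu + n_sd * s)
}

#' Full trait preparation pipeline
#'
#' Chains the standard preparation steps for regression-based heritability
#' analysis: optional log transform, adjustment for covariates, truncation of
#' outliers at `n_sd` SD, adjustment for principal components, and final
#' standardization to mean 0 and variance 1. By default truncation happens
#' after the covariate adjustment and before the PC adjustment; set
#' `truncate_after_pcs = TRUE` to truncate at the very end instead (the choice
#' is a configuration switch because published pipelines differ).
#'
#' @param trait Data frame with `sample_id`, `value` (or numeric vector).
#' @param covariates Optional covariate matrix / data frame.
#' @param pcs Optional `pc_result` or eigenvector matrix.
#' @param n_sd Truncation width in SDs (default 4); `Inf` disables truncation.
#' @param log,zero_value Passed to [transform_trait()].
#' @param truncate_after_pcs Truncate after (instead of before) PC adjustment.
#' @return Same shape as `trait`, prepared and standardized.
#' @export
prepare_trait <- function(trait, covariates = NULL, pcs = NULL, n_sd = 4,
                          log = FALSE, zero_value = NULL,
                          truncate_after_pcs = FALSE) {
  vec <- if (is.data.frame(trait)) trait$value else trait
  ids <- if (is.data.frame(trait)) trait[["sample_id"]] else NULL
  pcs <- align_pcs(pcs, ids)
  vec <- transform_trait(vec, log = log, zero_value = zero_value)
  if (!is.null(covariates)) {
    vec <- adjust_and_standardize(vec, covariates = covariates)
  }
  if (!truncate_after_pcs && is.finite(n_sd)) vec <- truncate_outliers(vec, n_sd)
  vec <- adjust_and_standardize(vec, pcs = pcs)
  if (truncate_after_pcs && is.finite(n_sd)) {
    vec <- adjust_and_standardize(truncate_outliers(vec, n_sd))
  }
  if (is.data.frame(trait)) {
    trait$value <- vec
    tibble::as_tibble(trait)
  } else {
    vec
  }
}

#' Drop rows flagged by boolean exclusion columns
#'
#' Cohort pipelines exclude individuals by status flags (pregnancy, medication,
#' non-fasting, ...). This helper removes rows where any of the named boolean
#' columns is `TRUE`.
#'
#' @param data Data frame.
#' @param exclude Character vector of logical column names.
#' @return Filtered tibble.
#' @export
filter_exclusions <- function(data, exclude) {
  check_columns(data, exclude, "data")
  keep <- !Reduce(`|`, lapply(exclude, function(cn) {
    v <- data[[cn]]
    if (!is.logical(v)) abort(sprintf("Column `%s` is not logical.", cn))
    v %in% TRUE
  }), accumulate = FALSE)
  tibble::as_tibble(data[keep, , drop = FALSE])
}
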