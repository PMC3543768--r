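#' Pairwise products of a standardized trait
#'
#' Builds all unordered sample pairs `j < k` with the product
#' `z_j * z_k` of their standardized trait values; these products are the
#' response of the regression-based heritability estimator.
#'
#' @param z Standardized trait: numeric vector named by sample id, or a data
#'   frame with `sample_id` and `value`. A warning is issued when the input
#'   does not have mean ~0 and variance ~1.
#' @return A tibble `sample_a`, `sample_b`, `product` with `choose(n, 2)` rows
#'   (matrix order, `sample_a` before `sample_b`).
#' @examples
#' pair_products(c(S1 = -1, S2 = 0, S3 = 1))
#' @export
pair_products <- function(z) {
  if (is.data.frame(z)) {
    check_columns(z, c("sample_id", "value"), "z")
    z <- setNames(z$value, z$sample_id)
  }
  stopifnot(is.numeric(z))
  n <- length(z)
  if (n < 2) abort("Need at least two samples.")
  if (abs(mean(z)) > 1e-6 || abs(var(z) - 1) > 0.01) {
    warn("`z` does not look standardized (mean 0, variance 1); see adjust_and_standardize().")
  }
  ids <- names(z) %||% sprintf("S%d", seq_len(n))
  ut <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  tibble::tibble(sample_a = ids[ut[, 1]], sample_b = ids[ut[, 2]],
                 product = unname(z[ut[, 1]] * z[ut[, 2]]))
}

#' Regression-based heritability from trait products and relatedness
#'
#' Regresses pairwise products of standardized trait values on pairwise
#' relatedness, restricted to pairs whose relatedness lies within a multiple
#' range of the average relatedness, and converts the slope to a heritability
#' estimate:
#' `h2 = slope * (1 - mean kinship)`, where the mean kinship is half the mean
#' relatedness over all supplied pairs (computed before the range
#' restriction). Estimates are clipped to `[0, 1]`: negative estimates become
#' 0 and estimates above 1 become 1. The slope, its standard error and the
#' p-value come from ordinary least squares treating pairs as independent
#' observations — an acknowledged approximation, since pairs sharing an
#' individual are dependent.
#'
#' The default range `(0, 2)` keeps pairs with relatedness between 0
#' (inclusive) and twice the average; presets `(0.5, 1.5)` and `(0.9, 1.1)`
#' restrict further, trading bias for a high fraction of clipped estimates.
#'
#' @param pairs Pair tibble from [pair_products()] (all retained pairs, i.e.
#'   after close-relative and PC-outlier exclusion).
#' @param A A [relatedness_matrix()] covering all samples in `pairs`.
#' @param range_mult Length-2 multipliers `(lo, hi)` of the mean relatedness
#'   defining the inclusive regression range.
#' @return An object of class `zuk_fit`; see [glance.zuk_fit()].
#' @export
zuk_estimate <- function(pairs, A, range_mult = c(0, 2)) {
  check_columns(pairs, c("sample_a", "sample_b", "product"), "pairs")
  stopifnot(is.numeric(range_mult), length(range_mult) == 2,
            range_mult[1] <= range_mult[2])
  ids <- rownames(A)
  ia <- match(pairs$sample_a, ids)
  ib <- match(pairs$sample_b, ids)
  if (anyNA(ia) || anyNA(ib)) abort("`pairs` mention samples absent from `A`.")
  rel <- unclass(A)[cbind(ia, ib)]
  zuk_fit_core(pairs$product, rel, range_mult)
}

# Closed-form OLS of products on relatedness over the restricted range.
zuk_fit_core <- function(products, rel, range_mult) {
  mean_rel <- mean(rel)
  lo <- range_mult[1] * mean_rel
  hi <- range_mult[2] * mean_rel
  in_range <- rel >= lo & rel <= hi
  n_in <- sum(in_range)
  if (n_in < 3) abort("Fewer than 3 pairs in the relatedness range.")
  x <- rel[in_range]
  y <- products[in_range]
  sxx <- sum((x - mean(x))^2)
  if (sxx <= 0) abort("Zero relatedness variance within the range.")
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * mean(x)
  resid <- y - intercept - slope * x
  df <- n_in - 2L
  se_slope <- sqrt(sum(resid^2) / df / sxx)
  t_stat <- slope / se_slope
  p_value <- 2 * pt(abs(t_stat), df, lower.tail = FALSE)
  mean_kinship <- mean_rel / 2
  raw <- slope * (1 - mean_kinship)
  structure(
    list(slope = slope, intercept = intercept, se_slope = se_slope,
         p_value = p_value, mean_relatedness = mean_rel,
         mean_kinship = mean_kinship, range = c(lo = lo, hi = hi),
         range_mult = range_mult, n_pairs = n_in,
         h2_raw = raw, h2 = min(max(raw, 0), 1),
         se_h2 = se_slope * (1 - mean_kinship),
         clipped = raw < 0 || raw > 1),
    class = "zuk_fit")
}

#' @export
print.zuk_fit <- function(x, ...) {
  cat(sprintf("<zuk_fit> h2 = %.3f%s (slope %.3f, se %.3f, p = %.3g)\n",
              x$h2, if (x$clipped) " [clipped]" else "", x$slope, x$se_slope,
              x$p_value))
  cat(sprintf("  %d pairs with relatedness in [%.4g, %.4g]; mean relatedness %.4g\n",
              x$n_pairs, x$range["lo"], x$range["hi"], x$mean_relatedness))
  invisible(x)
}

#' Tidy a regression heritability fit
#'
#' @param x A `zuk_fit`.
#' @param ... Unused.
#' @return Tibble with rows for the intercept and the relatedness slope
#'   (`estimate`, `std.error`, `p.value`).
#' @method tidy zuk_fit
#' @export
tidy.zuk_fit <- function(x, ...) {
  tibble::tibble(term = c("(Intercept)", "relatedness"),
                 estimate = c(x$intercept, x$slope),
                 std.error = c(NA, x$se_slope),
                 p.value = c(NA, x$p_value))
}

#' One-row summary of a regression heritability fit
#'
#' @param x A `zuk_fit`.
#' @param ... Unused.
#' @return A one-row tibble with `h2`, `h2_raw`, `clipped`, `slope`,
#'   `se_slope`, `p_value`, `mean_relatedness`, `mean_kinship`, `range_lo`,
#'   `range_hi`, `n_pairs`.
#' @method glance zuk_fit
#' @export
glance.zuk_fit <- function(x, ...) {
  tibble::tibble(h2 = x$h2, h2_raw = x$h2_raw, se_h2 = x$se_h2,
                 clipped = x$clipped,
                 slope = x$slope, se_slope = x$se_slope, p_value = x$p_value,
                 mean_relatedness = x$mean_relatedness,
                 mean_kinship = x$mean_kinship,
                 range_lo = x$range["lo"], range_hi = x$range["hi"],
                 n_pairs = x$n_pairs)
}

#' Plot trait products against relatedness with the fitted line
#'
#' @param object A `zuk_fit`.
#' @param pairs,A The pair tibble and relatedness matrix the fit was computed
#'   from (products are not stored in the fit).
#' @param bins Number of 2-d bins (pair clouds are large).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot zuk_fit
#' @export
autoplot.zuk_fit <- function(object, pairs, A, bins = 60, ...) {
  ids <- rownames(A)
  rel <- unclass(A)[cbind(match(pairs$sample_a, ids), match(pairs$sample_b, ids))]
  df <- tibble::tibble(relatedness = rel, product = pairs$product)
  df <- df[df$relatedness >= object$range["lo"] &
             df$relatedness <= object$range["hi"], ]
  ggplot2::ggplot(df, ggplot2::aes(.data$relatedness, .data$product)) +
    ggplot2::geom_bin2d(bins = bins) +
    ggplot2::geom_abline(intercept = object$intercept, slope = object$slope,
                         colour = "firebrick") +
    ggplot2::scale_fill_viridis_c(trans = "log10") +
    ggplot2::labs(x = "relatedness", y = "product of standardized traits") +
    ggplot2::theme_minimal()
}
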