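#' @import rlang
#' @importFrom stats coef complete.cases IQR lm median optimize pchisq pnorm
#'   pt qnorm quantile rbeta rbinom rexp rnorm runif sd setNames var
#' @importFrom utils head tail
#' @keywords internal
"_PACKAGE"

.datatable.aware <- TRUE

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Derive reproducible sub-seeds from a master seed
#'
#' All randomness in the package flows from a single master seed. Independent
#' random steps (allele frequencies, founder haplotypes, mosaics, phenotypes,
#' per-replicate draws) consume sub-seeds produced by this function: the master
#' seed seeds R's default generator once, and `n` integers are drawn from it.
#' Downstream code seeds a fresh stream from each sub-seed, so adding a new
#' consumer never perturbs existing streams as long as the order of consumers
#' is stable.
#'
#' @param seed Integer master seed.
#' @param n Number of sub-seeds to derive.
#' @return Integer vector of length `n`, each in `[1, 2^31 - 2]`.
#' @examples
#' derive_seeds(1, 3)
#' @export
derive_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  withr::with_seed(as.integer(seed), sample.int(.Machine$integer.max - 1L, n))
}

## Shared argument checks -----------------------------------------------------

check_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < lower || x > upper) {
    abort(sprintf("`%s` must be a single finite number in [%s, %s].",
                  name, format(lower), format(upper)))
  }
  invisible(x)
}

check_columns <- function(df, cols, name) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    abort(sprintf("`%s` is missing column(s): %s.", name,
                  paste(missing, collapse = ", ")))
  }
  invisible(df)
}
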