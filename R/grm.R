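#' Allele-sharing genomic relationship matrix
#'
#' The GCTA-style method-of-moments relatedness estimate from standardized
#' dosages. For a pair `j != k`
#' \deqn{A_{jk} = \frac{1}{N}\sum_i \frac{(x_{ij}-2p_i)(x_{ik}-2p_i)}{2p_i(1-p_i)}}
#' and on the diagonal `1 + f_j` with the allele-sharing inbreeding estimate
#' \deqn{\hat f_j = \frac{1}{N}\sum_i \frac{x_{ij}^2-(1+2p_i)x_{ij}+2p_i^2}{2p_i(1-p_i)}.}
#' `p_i` is the sample reference-allele frequency computed from the non-missing
#' dosages. Missing dosages are skipped pairwise: `N` is replaced by the number
#' of SNPs where both members of the pair are observed. SNPs monomorphic in the
#' sample are dropped with a warning (the denominator vanishes).
#'
#' @param geno Samples x SNPs dosage matrix (0/1/2, `NA` for missing) with
#'   sample ids as rownames, or a `population_sim` object.
#' @return A [relatedness_matrix()] with method `"allele_sharing"`.
#' @examples
#' g <- rbind(S1 = c(2, 1, 0), S2 = c(0, 1, 2), S3 = c(1, 1, 1))
#' grm(g)
#' @export
grm <- function(geno) {
  geno <- as_dosage_matrix(geno)
  n <- nrow(geno)
  if (n < 2) abort("`geno` must contain at least two samples.")
  all_missing <- rowSums(!is.na(geno)) == 0
  if (any(all_missing)) {
    abort(sprintf("Sample(s) with all-missing genotypes: %s.",
                  paste(head(rownames(geno)[all_missing], 5), collapse = ", ")))
  }
  p <- colMeans(geno, na.rm = TRUE) / 2
  mono <- p <= 0 | p >= 1
  if (any(mono)) {
    warn(sprintf("Dropping %d SNP(s) monomorphic in the sample.", sum(mono)))
    geno <- geno[, !mono, drop = FALSE]
    p <- p[!mono]
  }
  if (!ncol(geno)) abort("No polymorphic SNPs left.")
  denom <- 2 * p * (1 - p)
  Z <- sweep(geno, 2, 2 * p) / rep(sqrt(denom), each = n)
  if (anyNA(Z)) {
    obs <- !is.na(Z)
    Z0 <- Z
    Z0[!obs] <- 0
    A <- tcrossprod(Z0) / tcrossprod(obs + 0)
  } else {
    A <- tcrossprod(Z) / ncol(Z)
  }
  # diagonal: allele-sharing inbreeding estimate 1 + f_hat
  num <- geno^2 - sweep(geno, 2, 1 + 2 * p, `*`) + rep(2 * p^2, each = n)
  fhat <- rowMeans(sweep(num, 2, denom, `/`), na.rm = TRUE)
  diag(A) <- 1 + fhat
  relatedness_matrix(A, method = "allele_sharing")
}

as_dosage_matrix <- function(geno) {
  if (inherits(geno, "population_sim")) geno <- geno$genotypes
  stopifnot(is.matrix(geno), is.numeric(geno))
  if (is.null(rownames(geno))) abort("`geno` must have sample ids as rownames.")
  geno
}

#' Principal components of allele-sharing relatedness
#'
#' Eigendecomposition of the allele-sharing matrix with the diagonal replaced
#' by the standardized self-term `(1/N) sum_i (x_ij - 2p_i)^2 / (2p_i(1-p_i))`
#' (the same quadratic form as the off-diagonals evaluated at `j = k`), as used
#' for stratification adjustment. Eigenvector signs follow a deterministic
#' convention: the largest-magnitude loading of each component is positive.
#'
#' @param geno Dosage matrix or `population_sim` (see [grm()]).
#' @param k Number of components (default 20); reduced with a warning if it
#'   exceeds the available rank.
#' @return An object of class `pc_result`: list with `vectors` (samples x k,
#'   orthonormal), `values` (non-increasing eigenvalues), `k`.
#' @export
pca <- function(geno, k = 20) {
  geno <- as_dosage_matrix(geno)
  n <- nrow(geno)
  check_scalar_number(k, "k", lower = 1)
  if (k > min(dim(geno))) abort("`k` exceeds min(samples, SNPs).")
  p <- colMeans(geno, na.rm = TRUE) / 2
  keep <- p > 0 & p < 1
  g <- geno[, keep, drop = FALSE]
  p <- p[keep]
  Z <- sweep(g, 2, 2 * p) / rep(sqrt(2 * p * (1 - p)), each = n)
  if (anyNA(Z)) {
    obs <- !is.na(Z)
    Z0 <- Z
    Z0[!obs] <- 0
    A <- tcrossprod(Z0) / tcrossprod(obs + 0)
  } else {
    A <- tcrossprod(Z) / ncol(Z)
  }
  eig <- eigen(A, symmetric = TRUE)
  pos <- sum(eig$values > max(eig$values) * 1e-12)
  if (k > pos) {
    warn(sprintf("Requested %d components but rank is %d; returning %d.",
                 as.integer(k), pos, pos))
    k <- pos
  }
  vec <- eig$vectors[, seq_len(k), drop = FALSE]
  # deterministic sign: largest-magnitude loading positive
  for (j in seq_len(k)) {
    i <- which.max(abs(vec[, j]))
    if (vec[i, j] < 0) vec[, j] <- -vec[, j]
  }
  dimnames(vec) <- list(rownames(geno), paste0("PC", seq_len(k)))
  structure(list(vectors = vec, values = eig$values[seq_len(k)], k = as.integer(k)),
            class = "pc_result")
}

#' @export
print.pc_result <- function(x, ...) {
  cat(sprintf("<pc_result> %d samples x %d components; leading eigenvalues %s\n",
              nrow(x$vectors), x$k,
              paste(signif(head(x$values, 3), 3), collapse = ", ")))
  invisible(x)
}

#' @method tidy pc_result
#' @export
tidy.pc_result <- function(x, ...) {
  tibble::as_tibble(x$vectors, rownames = "sample_id") |>
    tidyr::pivot_longer(-"sample_id", names_to = "component",
                        values_to = "value")
}

#' Scatterplot of two principal components
#'
#' @param object A `pc_result`.
#' @param components Which two components to plot (default 1:2).
#' @param labels Optional per-sample grouping (named vector or factor in sample
#'   order) used for colour.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pc_result
#' @export
autoplot.pc_result <- function(object, components = c(1, 2), labels = NULL, ...) {
  df <- tibble::tibble(x = object$vectors[, components[1]],
                       y = object$vectors[, components[2]])
  if (!is.null(labels)) df$group <- as.factor(labels)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::labs(x = paste0("PC", components[1]), y = paste0("PC", components[2])) +
    ggplot2::theme_minimal()
  if (is.null(labels)) p + ggplot2::geom_point(alpha = 0.6)
  else p + ggplot2::geom_point(ggplot2::aes(colour = .data$group), alpha = 0.6)
}

#' Flag principal-component outliers
#'
#' A sample is flagged when, on any of the first `k` eigenvectors, its value
#' lies more than `multiplier` times the interquartile range away from the
#' median of that eigenvector. Eigenvectors with zero IQR flag nobody. The
#' standard pipeline removes the flagged samples and recomputes the components
#' once on the reduced set (see [pca_adjustment()]).
#'
#' @param pcs A `pc_result`.
#' @param k Number of leading eigenvectors to scan (default: all in `pcs`).
#' @param multiplier IQR multiplier (default 3).
#' @return Character vector of flagged sample ids.
#' @export
pc_outliers <- function(pcs, k = pcs$k, multiplier = 3) {
  stopifnot(inherits(pcs, "pc_result"))
  check_scalar_number(k, "k", lower = 1, upper = pcs$k)
  check_scalar_number(multiplier, "multiplier", lower = 0)
  flagged <- rep(FALSE, nrow(pcs$vectors))
  for (j in seq_len(k)) {
    v <- pcs$vectors[, j]
    iqr <- IQR(v)
    if (iqr == 0) next
    flagged <- flagged | abs(v - median(v)) > multiplier * iqr
  }
  rownames(pcs$vectors)[flagged]
}

#' Principal components with one round of outlier removal
#'
#' Computes `k` principal components, flags 3xIQR outliers on them, removes the
#' flagged samples, and recomputes the components once on the reduced set.
#'
#' @inheritParams pca
#' @inheritParams pc_outliers
#' @return List with `pcs` (final `pc_result` on the retained samples),
#'   `outliers` (removed sample ids), `samples` (retained ids).
#' @export
pca_adjustment <- function(geno, k = 20, multiplier = 3) {
  geno <- as_dosage_matrix(geno)
  k <- min(k, nrow(geno) - 1L, ncol(geno))
  first <- pca(geno, k)
  out <- pc_outliers(first, multiplier = multiplier)
  if (!length(out)) {
    return(list(pcs = first, outliers = character(0), samples = rownames(geno)))
  }
  keep <- setdiff(rownames(geno), out)
  list(pcs = pca(geno[keep, , drop = FALSE], min(k, length(keep) - 1L)),
       outliers = out, samples = keep)
}
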