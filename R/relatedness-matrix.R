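#' Construct a relatedness matrix
#'
#' A `relatedness_matrix` is a symmetric numeric matrix of pairwise relatedness
#' values (twice the realized kinship coefficient) with sample identifiers as
#' dimnames, a diagonal of `1 + f` (inbreeding coefficient `f`), and a tag
#' recording how it was built (`ibd_weighted`, `ibd_unweighted`,
#' `allele_sharing`, `x_chromosome`, `true_ibd`, ...).
#'
#' @param x Symmetric numeric matrix with identical row/column names.
#' @param method Character tag describing the construction method.
#' @return The matrix with class `relatedness_matrix` and a `method` attribute.
#' @export
relatedness_matrix <- function(x, method = "unspecified") {
  stopifnot(is.matrix(x), is.numeric(x), nrow(x) == ncol(x))
  if (is.null(rownames(x))) {
    abort("`x` must carry sample ids as dimnames.")
  }
  if (!identical(rownames(x), colnames(x))) {
    abort("Row and column names of `x` must be identical.")
  }
  if (max(abs(x - t(x))) > 1e-10) {
    abort("`x` must be symmetric.")
  }
  structure(x, method = method, class = c("relatedness_matrix", class(matrix())))
}

#' @export
print.relatedness_matrix <- function(x, ...) {
  off <- x[upper.tri(x)]
  cat(sprintf("<relatedness_matrix> %d samples, method '%s'\n",
              nrow(x), attr(x, "method")))
  cat(sprintf("  off-diagonal mean %.4g (range %.4g .. %.4g), mean diagonal %.4g\n",
              mean(off), min(off), max(off), mean(diag(x))))
  invisible(x)
}

#' Tidy a relatedness matrix into pair records
#'
#' @param x A [relatedness_matrix()].
#' @param diagonal Include the diagonal (self) entries? Default `FALSE`.
#' @param ... Unused.
#' @return A tibble with `sample_a`, `sample_b`, `value` (unordered pairs,
#'   `sample_a` before `sample_b` in matrix order).
#' @method tidy relatedness_matrix
#' @export
tidy.relatedness_matrix <- function(x, diagonal = FALSE, ...) {
  ids <- rownames(x)
  ut <- which(upper.tri(x, diag = diagonal), arr.ind = TRUE)
  tibble::tibble(sample_a = ids[ut[, 1]], sample_b = ids[ut[, 2]],
                 value = x[ut])
}

#' Heatmap of a relatedness matrix
#'
#' @param object A [relatedness_matrix()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot relatedness_matrix
#' @export
autoplot.relatedness_matrix <- function(object, ...) {
  ids <- rownames(object)
  df <- tidyr::expand_grid(sample_a = factor(ids, levels = ids),
                           sample_b = factor(ids, levels = rev(ids)))
  df$value <- as.vector(unclass(object))
  ggplot2::ggplot(df, ggplot2::aes(.data$sample_a, .data$sample_b,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "relatedness") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("Relatedness (%s)", attr(object, "method"))) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}

#' Write and read a relatedness matrix in GCTA-style text GRM format
#'
#' `write_grm()` writes `<prefix>.grm` (tab-separated triplets: 1-based index
#' of sample j, index of sample k <= j, number of units used, relatedness
#' value) and `<prefix>.grm.id` (family id, sample id; the family id is the
#' sample id). `read_grm()` reads the pair back.
#'
#' @param A A [relatedness_matrix()].
#' @param prefix Path prefix for the two files.
#' @param n_units Number of units (SNPs or map intervals) behind each value,
#'   recycled to the number of triplets.
#' @return `write_grm()` returns `prefix` invisibly; `read_grm()` returns a
#'   [relatedness_matrix()].
#' @export
write_grm <- function(A, prefix, n_units = 1L) {
  stopifnot(inherits(A, "relatedness_matrix"))
  ids <- rownames(A)
  lt <- which(lower.tri(A, diag = TRUE), arr.ind = TRUE) # j >= k
  trip <- data.frame(j = lt[, 1], k = lt[, 2],
                     n = rep_len(as.integer(n_units), nrow(lt)),
                     value = A[lt])
  trip <- trip[order(trip$j, trip$k), ]
  readr::write_tsv(trip, paste0(prefix, ".grm"), col_names = FALSE)
  readr::write_tsv(data.frame(fid = ids, iid = ids),
                   paste0(prefix, ".grm.id"), col_names = FALSE)
  invisible(prefix)
}

#' @param method Method tag to attach on read.
#' @rdname write_grm
#' @export
read_grm <- function(prefix, method = "unspecified") {
  ids <- readr::read_tsv(paste0(prefix, ".grm.id"),
                         col_names = c("fid", "iid"),
                         col_types = "cc", progress = FALSE)$iid
  trip <- readr::read_tsv(paste0(prefix, ".grm"),
                          col_names = c("j", "k", "n", "value"),
                          col_types = "iind", progress = FALSE)
  n <- length(ids)
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  A[cbind(trip$j, trip$k)] <- trip$value
  A[cbind(trip$k, trip$j)] <- trip$value
  relatedness_matrix(A, method = method)
}

#' Write/read a relatedness matrix as a square TSV
#'
#' First column `sample_id`, remaining columns one per sample.
#'
#' @inheritParams write_grm
#' @param path File path.
#' @export
write_relatedness_tsv <- function(A, path) {
  stopifnot(inherits(A, "relatedness_matrix"))
  df <- tibble::as_tibble(as.data.frame(unclass(A)))
  df <- dplyr::bind_cols(tibble::tibble(sample_id = rownames(A)), df)
  readr::write_tsv(df, path)
  invisible(path)
}

#' @rdname write_relatedness_tsv
#' @export
read_relatedness_tsv <- function(path, method = "unspecified") {
  df <- readr::read_tsv(path, col_types = readr::cols(
    sample_id = readr::col_character(), .default = readr::col_double()),
    progress = FALSE)
  A <- as.matrix(df[, -1])
  rownames(A) <- df$sample_id
  relatedness_matrix(A, method = method)
}

# Align a relatedness matrix (or plain named matrix) to a set of sample ids.
align_relatedness <- function(A, ids, name = "A") {
  stopifnot(is.matrix(A))
  if (is.null(rownames(A))) abort(sprintf("`%s` must have sample ids as dimnames.", name))
  missing <- setdiff(ids, rownames(A))
  if (length(missing)) {
    abort(sprintf("`%s` lacks sample(s): %s.", name,
                  paste(head(missing, 5), collapse = ", ")))
  }
  unclass(A)[ids, ids, drop = FALSE]
}
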