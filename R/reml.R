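#' Precompute the REML rotation for a relatedness matrix
#'
#' The single-component model `y = X beta + g + e` with
#' `Var(g) = sigma_g^2 A`, `Var(e) = sigma_e^2 I` is fitted by restricted
#' maximum likelihood after one eigendecomposition `A = U D U'`: in the rotated
#' basis the covariance is diagonal and the restricted likelihood can be
#' profiled over the heritability `h2 = sigma_g^2 / (sigma_g^2 + sigma_e^2)`
#' with a one-dimensional search. Building the kernel once and fitting many
#' traits against it (as simulation studies do) costs one decomposition total.
#'
#' @param A A [relatedness_matrix()] or symmetric numeric matrix with sample
#'   ids as dimnames.
#' @param X Fixed-effect design matrix (rows = samples of `A`, in order). An
#'   intercept column is added when no constant column is present.
#' @param psd_repair Eigenvalues of `A` below `-1e-8` are an error by default;
#'   set `TRUE` to clip negative eigenvalues to zero (nearest-PSD repair).
#' @return An object of class `reml_kernel`.
#' @export
reml_kernel <- function(A, X = NULL, psd_repair = FALSE) {
  ids <- rownames(A)
  if (is.null(ids)) abort("`A` must carry sample ids as dimnames.")
  A <- unclass(A)
  n <- nrow(A)
  X <- reml_design(X, n)
  if (qr(X)$rank < ncol(X)) abort("Fixed-effect design `X` is rank deficient.")
  eig <- eigen(A, symmetric = TRUE)
  tol <- 1e-8 * max(1, abs(eig$values[1]))
  if (eig$values[n] < -tol) {
    if (!psd_repair) {
      abort(sprintf(paste(
        "`A` has negative eigenvalue %.3g; it is not a valid covariance kernel.",
        "Use `psd_repair = TRUE` to clip negative eigenvalues to zero."),
        eig$values[n]))
    }
  }
  d <- pmax(eig$values, if (psd_repair) 0 else eig$values[n])
  structure(list(ids = ids, d = d, U = eig$vectors,
                 Xstar = crossprod(eig$vectors, X),
                 xnames = colnames(X), n = n, p = ncol(X)),
            class = "reml_kernel")
}

reml_design <- function(X, n) {
  if (is.null(X)) return(matrix(1, n, 1, dimnames = list(NULL, "(Intercept)")))
  X <- as.matrix(X)
  stopifnot(nrow(X) == n)
  storage.mode(X) <- "double"
  has_const <- any(apply(X, 2, function(cl) max(cl) - min(cl) < 1e-12))
  if (!has_const) X <- cbind(`(Intercept)` = 1, X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  X
}

#' Fit the single-component heritability model by REML
#'
#' Maximizes the restricted likelihood of `y = X beta + g + e`,
#' `Var(g) = sigma_g^2 A`, `Var(e) = sigma_e^2 I`, by profiling out the total
#' variance and the fixed effects and searching over `h2` in `[0, 1]`
#' (tolerance 1e-8). Variance components are recovered from the profiled
#' scale; the standard error of `h2` comes from the inverse
#' average-information matrix at the optimum via the delta method
#' (`se = "observed"` uses a numeric observed-information matrix instead).
#' The p-value for `h2 > 0` is a likelihood-ratio test against the model
#' without genetic effects; because the null lies on the boundary of the
#' parameter space the reference distribution is the mixture
#' `0.5 chi^2_0 + 0.5 chi^2_1` (see [lrt_h2()] for the plain-chi-square
#' variant).
#'
#' @param y Trait: numeric vector (optionally named by sample id) or a data
#'   frame with `sample_id` and `value`.
#' @param A A [relatedness_matrix()], plain symmetric matrix with sample-id
#'   dimnames, or a prebuilt [reml_kernel()]. When `y` carries sample ids and
#'   `A` is a matrix, `A` is aligned to `y`'s ids; mismatched ids are an error.
#' @param X Fixed-effect design (see [reml_kernel()]); ignored when `A` is
#'   already a kernel.
#' @param se `"average_information"` (default) or `"observed"`.
#' @param psd_repair Passed to [reml_kernel()].
#' @return An object of class `reml_fit`; see [glance.reml_fit()].
#' @examples
#' set.seed(1)
#' ids <- sprintf("S%02d", 1:60)
#' A <- diag(60); A[cbind(1:30 * 2 - 1, 1:30 * 2)] <- 0.5
#' A <- A + t(A) - diag(diag(A)); dimnames(A) <- list(ids, ids)
#' y <- as.vector(chol(A + diag(60)) %*% rnorm(60)) # some genetic signal
#' fit <- fit_reml(setNames(y, ids), relatedness_matrix(A, "pedigree"))
#' glance(fit)
#' @export
fit_reml <- function(y, A, X = NULL, se = c("average_information", "observed"),
                     psd_repair = FALSE) {
  se <- match.arg(se)
  if (is.data.frame(y)) {
    check_columns(y, "value", "y")
    y <- setNames(y$value, y[["sample_id"]])
  }
  stopifnot(is.numeric(y))
  if (inherits(A, "reml_kernel")) {
    kern <- A
    if (!is.null(names(y))) {
      if (!setequal(names(y), kern$ids)) {
        abort("Sample ids of `y` do not match the kernel's ids.")
      }
      y <- y[kern$ids]
    } else if (length(y) != kern$n) {
      abort("`y` length does not match the kernel.")
    }
  } else {
    if (!is.null(names(y))) {
      A <- align_relatedness(as.matrix(A), names(y))
    }
    kern <- reml_kernel(A, X, psd_repair = psd_repair)
  }
  n <- kern$n
  p <- kern$p
  ystar <- as.vector(crossprod(kern$U, unname(y)))

  pll <- function(h) reml_profile_loglik(h, ystar, kern)
  opt <- optimize(function(h) pll(h)$ll, interval = c(0, 1),
                  maximum = TRUE, tol = 1e-8)
  cand_h <- c(opt$maximum, 0, 1)
  cand_ll <- c(opt$objective, pll(0)$ll, pll(1)$ll)
  best <- which.max(cand_ll)
  h2 <- cand_h[best]
  at <- pll(h2)
  ll0 <- pll(0)$ll
  sigma_p2 <- at$rss / (n - p)
  sigma_g2 <- h2 * sigma_p2
  sigma_e2 <- (1 - h2) * sigma_p2
  boundary <- h2 < 1e-6 || h2 > 1 - 1e-6

  se_h2 <- reml_se_h2(sigma_g2, sigma_e2, ystar, kern, method = se)
  lrt <- max(0, 2 * (at$ll - ll0))
  p_value <- if (lrt <= 0) 1 else 0.5 * pchisq(lrt, df = 1, lower.tail = FALSE)

  structure(
    list(h2 = h2, se_h2 = se_h2, sigma_g2 = sigma_g2, sigma_e2 = sigma_e2,
         loglik = at$ll, loglik_null = ll0, lrt = lrt, p_value = p_value,
         beta = setNames(at$beta, kern$xnames),
         n = n, p = p, boundary = boundary,
         converged = is.finite(at$ll), se_method = se,
         kernel_ids = kern$ids),
    class = "reml_fit")
}

# Restricted log-likelihood profiled over the total variance, at heritability
# h. Works in the rotated basis where A is diagonal. Returns the profiled
# restricted log-likelihood (including constants, so values are comparable to
# a direct dense evaluation), the weighted RSS and the GLS fixed effects.
reml_profile_loglik <- function(h, ystar, kern) {
  w <- h * kern$d + (1 - h)
  if (any(w < 1e-12)) {
    return(list(ll = -Inf, rss = NA_real_, beta = rep(NA_real_, kern$p)))
  }
  sw <- sqrt(w)
  xw <- kern$Xstar / sw
  yw <- ystar / sw
  qx <- qr(xw)
  beta <- qr.coef(qx, yw)
  res <- qr.resid(qx, yw)
  rss <- sum(res^2)
  np <- kern$n - kern$p
  logdet_xtwix <- 2 * sum(log(abs(diag(qx$qr)[seq_len(kern$p)])))
  ll <- -0.5 * (sum(log(w)) + logdet_xtwix +
                  np * (1 + log(2 * pi * rss / np)))
  list(ll = ll, rss = rss, beta = beta)
}

# Standard error of h2 by the delta method from the inverse information matrix
# of (sigma_g2, sigma_e2) at the optimum. Average information by default;
# numeric observed information on request. Returns NA when the information
# matrix is singular (e.g. hard boundary cases).
reml_se_h2 <- function(sigma_g2, sigma_e2, ystar, kern, method) {
  total <- sigma_g2 + sigma_e2
  info <- tryCatch({
    if (method == "average_information") {
      w <- sigma_g2 * kern$d + sigma_e2
      sw <- sqrt(w)
      xw <- kern$Xstar / sw
      qx <- qr(xw)
      beta <- qr.coef(qx, ystar / sw)
      py <- (ystar - as.vector(kern$Xstar %*% beta)) / w
      proj <- function(u) {
        # P u in the rotated basis: W^-1 u - W^-1 X (X' W^-1 X)^-1 X' W^-1 u
        uw <- u / sw
        (uw - qr.fitted(qx, uw)) / sw
      }
      u <- list(kern$d * py, py)
      ai <- matrix(0, 2, 2)
      for (i in 1:2) for (j in i:2) {
        ai[i, j] <- ai[j, i] <- 0.5 * sum(u[[i]] * proj(u[[j]]))
      }
      ai
    } else {
      obs_information(sigma_g2, sigma_e2, ystar, kern)
    }
  }, error = function(e) NULL)
  if (is.null(info)) return(NA_real_)
  vc <- tryCatch(solve(info), error = function(e) NULL)
  if (is.null(vc)) return(NA_real_)
  grad <- c(sigma_e2, -sigma_g2) / total^2
  v <- drop(t(grad) %*% vc %*% grad)
  if (!is.finite(v) || v < 0) NA_real_ else sqrt(v)
}

# Restricted log-likelihood at absolute variance components (no profiling).
reml_loglik_abs <- function(sigma_g2, sigma_e2, ystar, kern) {
  w <- sigma_g2 * kern$d + sigma_e2
  if (any(w < 1e-300)) return(-Inf)
  sw <- sqrt(w)
  xw <- kern$Xstar / sw
  yw <- ystar / sw
  qx <- qr(xw)
  res <- qr.resid(qx, yw)
  logdet_xtwix <- 2 * sum(log(abs(diag(qx$qr)[seq_len(kern$p)])))
  -0.5 * (sum(log(w)) + logdet_xtwix + sum(res^2) +
            (kern$n - kern$p) * log(2 * pi))
}

obs_information <- function(sigma_g2, sigma_e2, ystar, kern) {
  th <- c(sigma_g2, sigma_e2)
  hstep <- pmax(1e-4 * pmax(abs(th), 1e-3), 1e-8)
  f <- function(t) reml_loglik_abs(max(t[1], 0), max(t[2], 1e-12), ystar, kern)
  H <- matrix(0, 2, 2)
  for (i in 1:2) for (j in 1:2) {
    ei <- ej <- c(0, 0)
    ei[i] <- hstep[i]
    ej[j] <- hstep[j]
    H[i, j] <- (f(th + ei + ej) - f(th + ei - ej) -
                  f(th - ei + ej) + f(th - ei - ej)) / (4 * hstep[i] * hstep[j])
  }
  -(H + t(H)) / 2
}

#' Likelihood-ratio p-value for h2 > 0
#'
#' Compares the fitted model to the model without genetic effects. The null
#' hypothesis `sigma_g^2 = 0` lies on the boundary of the parameter space, so
#' by default the reference distribution is the mixture
#' `0.5 chi^2_0 + 0.5 chi^2_1`: `p = 0.5 P(chi^2_1 > LRT)` for a positive
#' statistic and `p = 1` otherwise. `mixture = FALSE` uses the plain
#' `chi^2_1` tail (twice the mixture p-value, capped at 1), for comparison
#' with software that ignores the boundary.
#'
#' @param fit A [fit_reml()] result.
#' @param mixture Use the boundary mixture (default `TRUE`).
#' @return The p-value (scalar).
#' @export
lrt_h2 <- function(fit, mixture = TRUE) {
  stopifnot(inherits(fit, "reml_fit"))
  if (fit$lrt <= 0) return(1)
  p <- pchisq(fit$lrt, df = 1, lower.tail = FALSE)
  if (mixture) 0.5 * p else p
}

#' @export
print.reml_fit <- function(x, ...) {
  cat(sprintf("<reml_fit> h2 = %.3f (se %.3f), sigma_g2 = %.3f, sigma_e2 = %.3f\n",
              x$h2, x$se_h2, x$sigma_g2, x$sigma_e2))
  cat(sprintf("  REML loglik %.3f (null %.3f), LRT %.3f, p = %.3g, n = %d%s\n",
              x$loglik, x$loglik_null, x$lrt, x$p_value, x$n,
              if (x$boundary) " [boundary]" else ""))
  invisible(x)
}

#' Tidy a REML fit
#'
#' @param x A `reml_fit`.
#' @param ... Unused.
#' @return One row per parameter (`h2`, `sigma_g2`, `sigma_e2`, fixed effects)
#'   with `estimate` and, for `h2`, `std.error`.
#' @method tidy reml_fit
#' @export
tidy.reml_fit <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(term = c("h2", "sigma_g2", "sigma_e2"),
                   estimate = c(x$h2, x$sigma_g2, x$sigma_e2),
                   std.error = c(x$se_h2, NA, NA)),
    tibble::tibble(term = names(x$beta), estimate = unname(x$beta),
                   std.error = NA_real_))
}

#' One-row summary of a REML fit
#'
#' @param x A `reml_fit`.
#' @param ... Unused.
#' @return A one-row tibble with `h2`, `se_h2`, `sigma_g2`, `sigma_e2`,
#'   `loglik`, `loglik_null`, `lrt`, `p_value`, `n`, `boundary`, `converged`.
#' @method glance reml_fit
#' @export
glance.reml_fit <- function(x, ...) {
  tibble::tibble(h2 = x$h2, se_h2 = x$se_h2, sigma_g2 = x$sigma_g2,
                 sigma_e2 = x$sigma_e2, loglik = x$loglik,
                 loglik_null = x$loglik_null, lrt = x$lrt,
                 p_value = x$p_value, n = x$n, boundary = x$boundary,
                 converged = x$converged)
}
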