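# The no-major-gene linear mixed model
#   y = X beta + Z gamma + e,  Var(gamma) = sigma2_g K,  Var(e) = sigma2 I,
# written with the signal-to-noise ratio lambda = sigma2_g / sigma2 so that
# Var(y) = sigma2 (lambda Z K Z' + I) = sigma2 Sigma. Estimation follows the
# Henderson mixed-model route: whiten by Sigma^(-1/2), take the BLUE of beta
# and the BLUP of gamma, update the variance components by the EM-type
# moment formulas, and iterate on lambda.

#' Symmetric inverse square root of a positive-definite matrix
#'
#' Computes the symmetric matrix `B` with `B %*% A %*% B = I` via the
#' eigendecomposition of `A`. Eigenvalues are floored at `eigen_floor`
#' before inversion so near-singular inputs do not explode.
#'
#' @param A symmetric positive-definite matrix.
#' @param eigen_floor lower bound applied to eigenvalues.
#' @return symmetric matrix `B = A^(-1/2)`.
#' @examples
#' symmetric_inverse_sqrt(diag(c(4, 9)))  # diag(1/2, 1/3)
#' @export
symmetric_inverse_sqrt <- function(A, eigen_floor = 1e-12) {
  A <- as.matrix(A)
  .assert(nrow(A) == ncol(A), "A must be square")
  .assert(max(abs(A - t(A))) <= 1e-8 * max(1, max(abs(A))),
          "A must be symmetric")
  ev <- eigen((A + t(A)) / 2, symmetric = TRUE)
  d <- pmax(ev$values, eigen_floor)
  B <- ev$vectors %*% (t(ev$vectors) / sqrt(d))
  (B + t(B)) / 2
}

# Whitening cache: Sigma(lambda) = lambda Z K Z' + I has the low-rank
# eigenstructure of Z L (L a Cholesky factor of K), so one thin SVD serves
# every lambda. Sigma^(-1/2) x = x + U diag((1+lambda a)^(-1/2) - 1) U'x.
# This is the Woodbury-style S x S route; it agrees with the dense n x n
# eigendecomposition to numerical precision (asserted in the test suite).
.sigma_cache <- function(Z, kinship) {
  K <- as.matrix(kinship)
  Ks <- (K + t(K)) / 2
  ch <- tryCatch(chol(Ks), error = function(e) NULL)
  if (is.null(ch)) {
    stop("kinship matrix is not positive definite; add a small diagonal jitter",
         call. = FALSE)
  }
  sv <- svd(Z %*% t(ch), nv = 0)
  keep <- sv$d > 1e-12 * max(sv$d)
  list(U = sv$u[, keep, drop = FALSE], a = sv$d[keep]^2,
       n = nrow(Z), S = ncol(Z), Kinv = chol2inv(ch))
}

# Apply Sigma(lambda)^(-1/2) to the columns of X.
.whiten <- function(cache, lambda, X) {
  X <- as.matrix(X)
  if (lambda == 0) return(X)
  cc <- 1 / sqrt(1 + lambda * cache$a) - 1
  X + cache$U %*% ((crossprod(cache$U, X)) * cc)
}

.sigma_inv_sqrt_full <- function(cache, lambda) {
  .whiten(cache, lambda, diag(cache$n))
}

#' Fit the no-major-gene mixed model at a fixed signal-to-noise ratio
#'
#' Single-pass Henderson-type fit with `lambda` held fixed: whitens by
#' `Sigma(lambda)^(-1/2)`, computes the BLUE
#' `beta = (W'W)^- W'v` (generalized inverse), the BLUP
#' `gamma = lambda K Z' Sigma^(-1/2) (v - W beta)`, the error variance
#' `sigma2 = ||v - W beta||^2 / (n - rank(W))`, and the polygenic variance
#' by the EM-type moment formula
#' `sigma2_g = (gamma' K^(-1) gamma + sigma2 tr(K^(-1) C)) / S` with
#' `C = (Z'MZ + (lambda K)^(-1))^(-1)` and `M = I - X (X'X)^- X'`.
#' At `lambda = 0` the whitening is the identity, the fit is ordinary least
#' squares, and `gamma` and `sigma2_g` are 0 by convention.
#'
#' @param y numeric phenotype vector (length n).
#' @param X fixed-effect design matrix (n x p); `NULL` for an intercept.
#' @param Z strain incidence matrix (n x S), one unit entry per row.
#' @param kinship S x S positive-definite kinship matrix.
#' @param lambda fixed signal-to-noise ratio, >= 0.
#' @param keep_sigma if `TRUE`, store the dense n x n whitening matrix in
#'   the fit (needed by downstream consumers of `sigma_inv_sqrt`).
#' @param cache internal whitening cache; recomputed when `NULL`.
#' @return an object of class `rcs_mixed_fit` with elements `beta_hat`,
#'   `gamma_hat`, `sigma2_hat`, `sigma2_g_hat`, `lam` (the ratio used for
#'   whitening), `lam_hat` (= `sigma2_g_hat / sigma2_hat`), `W`, `v`,
#'   `resid_w` (whitened residuals), `rank_W`, `sigma_inv_sqrt` (when
#'   requested), `n_iter`, `converged`.
#' @seealso [fit_null_mixed()] for the iterative estimate of `lambda`.
#' @export
fit_mixed_given_lambda <- function(y, X = NULL, Z, kinship, lambda,
                                   keep_sigma = TRUE, cache = NULL) {
  y <- as.numeric(y)
  n <- length(y)
  Z <- as.matrix(Z)
  .assert(nrow(Z) == n, "Z must have one row per observation")
  S <- ncol(Z)
  if (is.null(X)) X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  X <- as.matrix(X)
  .assert(lambda >= 0, "lambda must be non-negative")
  if (is.null(cache)) cache <- .sigma_cache(Z, kinship)

  W <- .whiten(cache, lambda, X)
  v <- drop(.whiten(cache, lambda, y))
  WtW <- crossprod(W)
  WtW_pinv <- .pinv(WtW)
  rank_W <- qr(W)$rank
  .assert(n > rank_W, "need more observations than fixed-effect rank")
  beta <- drop(WtW_pinv %*% crossprod(W, v))
  r <- v - drop(W %*% beta)
  sigma2 <- sum(r^2) / (n - rank_W)
  if (sigma2 <= 1e-12 * max(1, mean(y)^2)) {
    stop("degenerate fit: residual variance is zero (constant response?)",
         call. = FALSE)
  }

  if (lambda > 0) {
    # BLUP: gamma = G Z' Sigma^(-1) (y - X beta) with G = lambda K; the inner
    # Sigma^(-1/2) applied to the already-whitened residual gives Sigma^(-1).
    K <- as.matrix(kinship)
    gamma <- lambda * drop(K %*% crossprod(Z, .whiten(cache, lambda, r)))
    # EM-type moment update for the polygenic variance.
    XtX_pinv <- .pinv(crossprod(X))
    MZ <- Z - X %*% (XtX_pinv %*% crossprod(X, Z))
    ZMZ <- crossprod(Z, MZ)
    Ginv <- cache$Kinv / lambda
    C <- solve(ZMZ + Ginv)
    sigma2_g <- (drop(crossprod(gamma, cache$Kinv %*% gamma)) +
                   sigma2 * sum(cache$Kinv * C)) / S
  } else {
    gamma <- rep(0, S)
    sigma2_g <- 0
  }

  structure(list(
    beta_hat = beta,
    gamma_hat = stats::setNames(gamma, colnames(Z)),
    sigma2_hat = sigma2,
    sigma2_g_hat = sigma2_g,
    lam = lambda,
    lam_hat = sigma2_g / sigma2,
    W = W, v = v, resid_w = r,
    X = X, Z = Z, n = n, rank_W = rank_W,
    sigma_inv_sqrt = if (keep_sigma) .sigma_inv_sqrt_full(cache, lambda) else NULL,
    cache = cache,
    n_iter = 1L, converged = NA), class = "rcs_mixed_fit")
}

#' Fit the null mixed model with iterated signal-to-noise ratio
#'
#' Repeats [fit_mixed_given_lambda()] with `lambda` replaced by its current
#' estimate `sigma2_g_hat / sigma2_hat` (clamped at 0) until the relative
#' change in `lambda` falls below `tol` or `max_iter` is reached. A
#' non-convergent fit is returned with `converged = FALSE` and a warning,
#' never silently truncated.
#'
#' @inheritParams fit_mixed_given_lambda
#' @param lam_init starting value for the ratio.
#' @param tol relative convergence tolerance on `lambda`.
#' @param max_iter iteration cap.
#' @return an `rcs_mixed_fit` whose `lam` is the converged signal-to-noise
#'   estimate, with `n_iter` and `converged` filled in.
#' @export
fit_null_mixed <- function(y, X = NULL, Z, kinship, lam_init = 1,
                           tol = 1e-6, max_iter = 200, keep_sigma = TRUE,
                           cache = NULL) {
  .assert(lam_init >= 0, "lam_init must be non-negative")
  .assert(tol > 0 && max_iter >= 1, "tol and max_iter must be positive")
  if (is.null(cache)) cache <- .sigma_cache(as.matrix(Z), kinship)
  lam <- lam_init
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    fit <- fit_mixed_given_lambda(y, X, Z, kinship, lam,
                                  keep_sigma = FALSE, cache = cache)
    lam_new <- max(0, fit$lam_hat)
    if (abs(lam_new - lam) <= tol * max(1, lam)) {
      lam <- lam_new
      converged <- TRUE
      break
    }
    lam <- lam_new
  }
  fit <- fit_mixed_given_lambda(y, X, Z, kinship, lam,
                                keep_sigma = keep_sigma, cache = cache)
  fit$n_iter <- iter
  fit$converged <- converged
  if (!converged) {
    warning(sprintf(
      "signal-to-noise iteration did not converge after %d iterations (lambda = %.4g)",
      iter, lam), call. = FALSE)
  }
  fit
}

#' @export
print.rcs_mixed_fit <- function(x, ...) {
  cat("RCS null mixed-model fit\n")
  cat(sprintf("  n = %d, strains = %d\n", x$n, ncol(x$Z)))
  cat(sprintf("  beta:        %s\n",
              paste(sprintf("%.4f", x$beta_hat), collapse = ", ")))
  cat(sprintf("  sigma2:      %.4f\n", x$sigma2_hat))
  cat(sprintf("  sigma2_g:    %.4f\n", x$sigma2_g_hat))
  cat(sprintf("  lambda:      %.4f (%d iterations, converged: %s)\n",
              x$lam, x$n_iter, x$converged))
  invisible(x)
}
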