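# Genome-wide corrected p-values by the max-statistic (union-intersection)
# bootstrap. The observed z-set is compared against R resampled draws of
# z*_max = max_m z*_m; the corrected p-value of marker m is the fraction of
# resamples with z_m <= z*_max (ties count as acceptance).

.BOOT_CHUNK <- 2000L  # resamples per matrix batch; fixed so that results do
                      # not depend on memory-motivated chunking

#' Leverage-adjusted whitened residuals
#'
#' Residuals `r = v - W beta` of the null whitened model, rescaled by
#' `(1 - h_ii)^(-e)` where `h_ii` are the diagonal entries of the whitened
#' hat matrix `W (W'W)^- W'`, so that the resampling pool has (approximately)
#' the variance of the model errors. The default exponent 1/2 restores the
#' residual variance exactly under homoscedasticity; `exponent = "one"`
#' applies the full `(1 - h_ii)^(-1)` factor instead. Residuals are
#' mean-centered by default so pseudo-responses are unbiased.
#'
#' @param null_fit an `rcs_mixed_fit`.
#' @param exponent `"half"` (variance-preserving, default) or `"one"`.
#' @param center mean-center the adjusted residuals?
#' @return an object of class `rcs_residuals` with elements `eps_tilde`,
#'   `leverages`, `D` (the per-observation adjustment factors), `centered`.
#' @export
leverage_adjusted_residuals <- function(null_fit, exponent = c("half", "one"),
                                        center = TRUE) {
  exponent <- match.arg(exponent)
  .assert(inherits(null_fit, "rcs_mixed_fit"),
          "null_fit must come from fit_null_mixed()")
  W <- null_fit$W
  qrW <- qr(W)
  Qthin <- qr.Q(qrW)[, seq_len(qrW$rank), drop = FALSE]
  h <- rowSums(Qthin^2)
  if (any(h >= 1 - 1e-12)) {
    stop("degenerate leverage: some h_ii are (numerically) 1", call. = FALSE)
  }
  e <- if (exponent == "half") 0.5 else 1
  D <- (1 - h)^(-e)
  eps <- null_fit$resid_w * D
  if (center) eps <- eps - mean(eps)
  structure(list(eps_tilde = eps, leverages = h, D = D, centered = center,
                 exponent = exponent),
            class = "rcs_residuals")
}

#' Draw a whitened pseudo-response
#'
#' Resamples the leverage-adjusted residuals with replacement and adds them
#' to the fitted whitened mean: `v* = W beta + eps*`.
#'
#' @param null_fit an `rcs_mixed_fit`.
#' @param residuals an `rcs_residuals` from the same fit.
#' @param seed integer seed.
#' @return numeric vector `v*` of length n.
#' @export
draw_pseudo_observations <- function(null_fit, residuals, seed = NULL) {
  .assert(inherits(residuals, "rcs_residuals"),
          "residuals must come from leverage_adjusted_residuals()")
  n <- null_fit$n
  .assert(length(residuals$eps_tilde) == n,
          "residuals do not match the fit")
  if (!is.null(seed)) set.seed(seed)
  idx <- sample.int(n, n, replace = TRUE)
  drop(null_fit$W %*% null_fit$beta_hat) + residuals$eps_tilde[idx]
}

# Shared tail of both bootstrap procedures: given the observed scan and a
# generator of per-chunk response matrices (already in the whitened scale of
# the scan), accumulate z*_max draws and acceptance counts.
.boot_run <- function(scan_obs, R, make_V, scan_V) {
  keep <- !scan_obs$skipped
  if (!any(keep)) stop("all markers are skipped; nothing to test", call. = FALSE)
  z_obs <- scan_obs$z
  z_max <- numeric(0)
  done <- 0L
  while (done < R) {
    b <- min(.BOOT_CHUNK, R - done)
    V <- make_V(b)
    z_mat <- scan_V(V)            # M x b
    z_mat[!keep, ] <- -Inf
    z_max <- c(z_max, apply(z_mat, 2, max))
    done <- done + b
  }
  srt <- sort(z_max)
  counts <- integer(nrow(scan_obs))
  counts[keep] <- R - findInterval(z_obs[keep], srt, left.open = TRUE)
  p <- rep(NA_real_, nrow(scan_obs))
  p[keep] <- counts[keep] / R
  list(counts = counts, p = p, z_max = z_max)
}

.boot_result <- function(scan_obs, run, R, seed, method, smooth) {
  markers <- as.data.frame(scan_obs)
  markers$count <- run$counts
  markers$p <- run$p
  if (smooth) markers$p <- ifelse(is.na(run$p), NA, (run$counts + 1) / (R + 1))
  markers$neglog10_p <- -log10(markers$p)
  structure(list(markers = markers, R = R, z_max_draws = run$z_max,
                 seed = seed, method = method, smooth = smooth),
            class = "rcs_bootstrap")
}

#' Raw-phenotype bootstrap for the naive regression scan
#'
#' Computes the observed z-set with [naive_scan()], then draws `R` full
#' resamples of the raw phenotype vector (sampling n values with
#' replacement), rescans each, and records `z*_max` over non-skipped
#' markers. The genome-wide corrected p-value of marker m is
#' `#{r : z_m <= z*_max,r} / R`. Valid when phenotypes are exchangeable
#' under the null — i.e. when there is no polygenic background or a single
#' observation per strain.
#'
#' @inheritParams naive_scan
#' @param R number of bootstrap resamples.
#' @param seed integer seed driving the resampling.
#' @param smooth if `TRUE`, report `(count + 1) / (R + 1)` instead of the
#'   raw `count / R`.
#' @return an object of class `rcs_bootstrap`: `markers` (per-marker scan
#'   statistics plus `count`, `p`, `neglog10_p`), `R`, `z_max_draws`,
#'   `seed`, `method`.
#' @export
naive_bootstrap <- function(panel, phenotypes, R = 10000, seed = NULL,
                            variant = c("t", "tprime"), smooth = FALSE) {
  variant <- match.arg(variant)
  .assert(R >= 1, "R must be at least 1")
  Q <- .individual_genotypes(panel, phenotypes)
  y <- as.numeric(phenotypes$y)
  n <- length(y)
  W <- matrix(1, n, 1)
  scan_obs <- naive_scan(panel, phenotypes, variant = variant)
  if (!is.null(seed)) set.seed(seed)
  run <- .boot_run(
    scan_obs, R,
    make_V = function(b) matrix(y[sample.int(n, n * b, replace = TRUE)], n, b),
    scan_V = function(V) .scan_engine(W, V, Q, variant = variant)$z)
  .boot_result(scan_obs, run, R, seed, "naive", smooth)
}

#' Residual bootstrap for the mixed-model scan
#'
#' Step 0 fits the null mixed model (no major gene) to obtain the
#' signal-to-noise estimate, the whitening transform and the
#' leverage-adjusted whitened residuals; Step 1 computes the observed z-set
#' with [mixed_scan()] (whitening held fixed); Steps 2-3 draw `R` whitened
#' pseudo-responses `v* = W beta + eps*` by resampling the adjusted
#' residuals with replacement and refit the per-marker whitened major-gene
#' models on each (the signal-to-noise ratio and whitening are not
#' re-estimated within resamples); Step 4 converts acceptance counts of
#' `z_m <= z*_max` into genome-wide corrected p-values.
#'
#' @inheritParams naive_bootstrap
#' @param kinship S x S positive-definite kinship matrix, normally the
#'   genomic estimate ([genomic_kinship()]).
#' @param exponent leverage-adjustment exponent, see
#'   [leverage_adjusted_residuals()].
#' @param null_fit optionally, a precomputed `rcs_mixed_fit`; when `NULL`
#'   the null model is fitted here.
#' @param ... further arguments passed to [fit_null_mixed()].
#' @return an `rcs_bootstrap`; also carries `null_fit` and
#'   `null_converged`.
#' @export
mixed_bootstrap <- function(panel, phenotypes, kinship, R = 10000,
                            seed = NULL, exponent = c("half", "one"),
                            variant = c("t", "tprime"), smooth = FALSE,
                            null_fit = NULL, ...) {
  variant <- match.arg(variant)
  exponent <- match.arg(exponent)
  .assert(R >= 1, "R must be at least 1")
  y <- as.numeric(phenotypes$y)
  n <- length(y)
  Z <- .incidence(phenotypes$strain_id, panel$strain_id)
  if (is.null(null_fit)) {
    null_fit <- withCallingHandlers(
      fit_null_mixed(y, NULL, Z, kinship, keep_sigma = anyNA(panel$genotypes), ...),
      warning = function(w) invokeRestart("muffleWarning"))
  }
  scan_obs <- mixed_scan(panel, phenotypes, null_fit, variant = variant)
  res <- leverage_adjusted_residuals(null_fit, exponent = exponent)
  eps <- res$eps_tilde
  mean_w <- drop(null_fit$W %*% null_fit$beta_hat)
  Q <- .individual_genotypes(panel, phenotypes)
  lam <- null_fit$lam
  cache <- null_fit$cache
  whiten <- if (lam == 0) NULL else function(X) .whiten(cache, lam, X)
  bw_sub <- NULL
  if (lam > 0 && anyNA(Q)) {
    Bw <- if (is.null(null_fit$sigma_inv_sqrt)) {
      .sigma_inv_sqrt_full(cache, lam)
    } else {
      null_fit$sigma_inv_sqrt
    }
    bw_sub <- function(rows) Bw[rows, rows, drop = FALSE]
  }
  if (!is.null(seed)) set.seed(seed)
  run <- .boot_run(
    scan_obs, R,
    make_V = function(b) {
      mean_w + matrix(eps[sample.int(n, n * b, replace = TRUE)], n, b)
    },
    scan_V = function(V) {
      .scan_engine(null_fit$W, V, Q, whiten = whiten, bw_sub = bw_sub,
                   variant = variant)$z
    })
  out <- .boot_result(scan_obs, run, R, seed, "mixed", smooth)
  out$null_fit <- null_fit
  out$null_converged <- null_fit$converged
  if (isFALSE(null_fit$converged)) {
    warning("null mixed-model fit did not converge; bootstrap proceeds with its final estimates",
            call. = FALSE)
  }
  out
}

#' @export
print.rcs_bootstrap <- function(x, ...) {
  cat(sprintf("%s-model max-statistic bootstrap: R = %d resamples\n",
              x$method, x$R))
  mk <- x$markers[!x$markers$skipped, ]
  cat(sprintf("  min genome-wide p = %g at %s (chr %s)\n",
              min(mk$p), mk$marker[which.min(mk$p)],
              mk$chromosome[which.min(mk$p)]))
  cat(sprintf("  markers with p <= 0.01: %d of %d\n",
              sum(mk$p <= 0.01), nrow(mk)))
  invisible(x)
}

#' Identify significant peaks in a genome-wide p-value profile
#'
#' A peak is the minimum-p marker of a maximal run of consecutive markers
#' (within one chromosome) whose genome-wide corrected p-values are at or
#' below `threshold`. Skipped markers break runs.
#'
#' @param result an `rcs_bootstrap`, or a data frame with columns `marker`,
#'   `chromosome`, `position` and `p`.
#' @param threshold genome-wide significance level in (0, 1).
#' @return a data frame with one row per peak: `marker`, `chromosome`,
#'   `position`, `p`.
#' @export
count_significant_peaks <- function(result, threshold = 0.01) {
  .assert(threshold > 0 && threshold < 1, "threshold must lie in (0, 1)")
  mk <- if (inherits(result, "rcs_bootstrap")) result$markers else result
  sig <- !is.na(mk$p) & mk$p <= threshold
  out <- mk[0, c("marker", "chromosome", "position", "p")]
  if (!any(sig)) return(out)
  run_id <- cumsum(c(TRUE, diff(as.integer(sig)) != 0 |
                       mk$chromosome[-1] != mk$chromosome[-nrow(mk)]))
  for (r in unique(run_id[sig])) {
    rows <- which(run_id == r & sig)
    best <- rows[which.min(mk$p[rows])]
    out <- rbind(out, mk[best, c("marker", "chromosome", "position", "p")])
  }
  rownames(out) <- NULL
  out
}
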