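# Per-marker association statistics. Both scans reduce, in a suitable
# coordinate system, to an OLS fit of the (whitened) response on the
# (whitened) design augmented with the (whitened) BB-indicator column q_m.
# The naive scan is the special case with identity whitening. The absolute
# t-statistic is mapped to a z-score so that markers with different degrees
# of freedom (from missing genotypes) share a common genome-wide baseline.

#' Transform an absolute t-statistic to a z-score
#'
#' `z = t (1 - 1/(4 nu)) (1 + t^2/(2 nu))^(-1/2)`. The transform is computed
#' in the algebraically equivalent form `(1 - 1/(4 nu)) / sqrt(1/t^2 +
#' 1/(2 nu))` so that `t = Inf` maps to the finite limit `sqrt(2 nu) (1 -
#' 1/(4 nu))` and `t = 0` maps to 0. As `nu -> Inf`, `z -> t`.
#'
#' @param t non-negative t-statistic(s).
#' @param nu degrees of freedom, >= 1 (recycled against `t`).
#' @return z-score(s), same length as `t`.
#' @examples
#' t_to_z(2, 10)  # about 1.7801
#' @export
t_to_z <- function(t, nu) {
  .assert(all(nu >= 1), "degrees of freedom must be at least 1")
  .assert(all(t >= 0), "t must be non-negative")
  z <- (1 - 1 / (4 * nu)) / sqrt(1 / t^2 + 1 / (2 * nu))
  z[t == 0] <- 0
  z
}

# Core engine. Computes, for every marker column of Q (raw 0/1/NA genotype
# indicators, n x M) and every response column of V (n x B, already in the
# whitened scale), the signed effect, its t-statistic and the z-score of the
# model  response ~ W + whitened(q_m).  Markers with no missing genotypes are
# processed in one batch of matrix products; markers with missing genotypes
# drop the affected rows from the whitened system (the whitening of q is
# restricted to the retained rows) and are handled one at a time, vectorized
# across responses.
#
# W: n x p whitened fixed design. whiten: function(X) applying Sigma^(-1/2)
# (identity when NULL). bw_sub: function(rows) returning the corresponding
# submatrix of Sigma^(-1/2) (identity when NULL). variant: "t" uses the
# per-marker residual variance, "tprime" the null-model (W-only) variance.
.scan_engine <- function(W, V, Q, whiten = NULL, bw_sub = NULL,
                         variant = c("t", "tprime")) {
  variant <- match.arg(variant)
  n <- nrow(Q)
  M <- ncol(Q)
  V <- as.matrix(V)
  B <- ncol(V)
  W <- as.matrix(W)
  p_rank <- qr(W)$rank
  WtW_pinv <- .pinv(crossprod(W))
  proj <- function(A, Wm = W, pinv = WtW_pinv) {
    A - Wm %*% (pinv %*% crossprod(Wm, A))
  }

  xi <- matrix(NA_real_, M, B)
  se <- matrix(NA_real_, M, B)
  tt <- matrix(NA_real_, M, B)
  n_used <- integer(M)
  nu <- rep(NA_real_, M)
  skipped <- rep(TRUE, M)

  obs <- !is.na(Q)
  n_obs <- colSums(obs)
  complete <- which(n_obs == n)
  partial <- which(n_obs < n)

  fill <- function(cols, G, PGv, gPg, Vc, PVc, n_o, rk) {
    # G, PG etc restricted to the rows in use; Vc the matching response rows.
    nu_c <- n_o - rk - 1
    ok <- gPg > 1e-8 * n_o & nu_c >= 1
    if (!any(ok)) return(invisible())
    cols <- cols[ok]
    gPg <- gPg[ok]
    gPv <- PGv[ok, , drop = FALSE]
    vPv <- colSums(Vc * PVc)
    vPv_row <- matrix(vPv, length(cols), B, byrow = TRUE)
    xi_blk <- gPv / gPg
    rss <- pmax(vPv_row - gPv^2 / gPg, 0)
    s2 <- rss / nu_c
    if (variant == "tprime") {
      s2_stat <- matrix(vPv / (n_o - rk), length(cols), B, byrow = TRUE)
    } else {
      s2_stat <- s2
    }
    denom <- sqrt(s2_stat * gPg)
    t_blk <- ifelse(gPv == 0, 0, abs(gPv) / denom)
    t_blk[!is.finite(t_blk) & abs(gPv) > 0] <- Inf
    xi[cols, ] <<- xi_blk
    se[cols, ] <<- sqrt(s2 / gPg)
    tt[cols, ] <<- t_blk
    n_used[cols] <<- n_o
    nu[cols] <<- nu_c
    skipped[cols] <<- FALSE
    invisible()
  }

  if (length(complete)) {
    Qc <- Q[, complete, drop = FALSE]
    storage.mode(Qc) <- "double"
    G <- if (is.null(whiten)) Qc else whiten(Qc)
    PG <- proj(G)
    gPg <- colSums(G * PG)
    PV <- proj(V)
    # g'Pv computed against the projected response so that an exactly null
    # projected phenotype yields exactly zero statistics
    PGv <- crossprod(G, PV)
    fill(complete, G, PGv, gPg, V, PV, n, p_rank)
  }

  for (m in partial) {
    o <- which(obs[, m])
    if (length(o) < 3) next
    q_o <- as.numeric(Q[o, m])
    g_o <- if (is.null(bw_sub)) q_o else drop(bw_sub(o) %*% q_o)
    W_o <- W[o, , drop = FALSE]
    rk_o <- qr(W_o)$rank
    pinv_o <- .pinv(crossprod(W_o))
    V_o <- V[o, , drop = FALSE]
    Pg <- g_o - drop(W_o %*% (pinv_o %*% crossprod(W_o, g_o)))
    PV_o <- proj(V_o, W_o, pinv_o)
    fill(m, matrix(g_o), matrix(crossprod(g_o, PV_o), 1), sum(g_o * Pg),
         V_o, PV_o, length(o), rk_o)
  }

  z <- tt
  ok <- !skipped
  if (any(ok)) {
    z[ok, ] <- t_to_z(tt[ok, , drop = FALSE],
                      matrix(nu[ok], sum(ok), B))
  }
  list(xi = xi, se = se, t = tt, z = z, nu = nu, n_used = n_used,
       skipped = skipped, rank_W = p_rank)
}

.scan_result <- function(map, eng, variant, model) {
  out <- data.frame(
    marker = map$marker,
    chromosome = map$chromosome,
    position = map$position,
    n_used = eng$n_used,
    xi_hat = eng$xi[, 1],
    se = eng$se[, 1],
    t = eng$t[, 1],
    nu = eng$nu,
    z = eng$z[, 1],
    skipped = eng$skipped,
    stringsAsFactors = FALSE)
  structure(out, class = c("rcs_scan", "data.frame"),
            variant = variant, model = model)
}

#' Naive per-marker regression scan
#'
#' At each marker, individuals inherit their strain's genotype, individuals
#' with a missing genotype are dropped, and the phenotype is regressed on an
#' intercept plus the BB-genotype indicator by ordinary least squares,
#' ignoring the polygenic background. `t = |xi_hat| / se(xi_hat)` with
#' `nu = n_used - 2` degrees of freedom is mapped to a z-score. The
#' `"tprime"` variant replaces the per-marker residual variance by the
#' null-model (intercept-only) variance. Markers that are monomorphic after
#' dropping missing genotypes, or retain fewer than 3 individuals, are
#' flagged `skipped`.
#'
#' @param panel an `rcs_panel`.
#' @param phenotypes an `rcs_phenotypes` data frame (or any data frame with
#'   `strain_id` and `y`).
#' @param variant `"t"` (default) or `"tprime"`.
#' @return a data frame of class `rcs_scan` with one row per marker:
#'   `marker`, `chromosome`, `position`, `n_used`, `xi_hat`, `se`, `t`,
#'   `nu`, `z`, `skipped`.
#' @export
naive_scan <- function(panel, phenotypes, variant = c("t", "tprime")) {
  variant <- match.arg(variant)
  .assert(inherits(panel, "rcs_panel"), "panel must be an rcs_panel")
  Q <- .individual_genotypes(panel, phenotypes)
  y <- as.numeric(phenotypes$y)
  W <- matrix(1, length(y), 1)
  eng <- .scan_engine(W, matrix(y), Q, variant = variant)
  .scan_result(panel$map, eng, variant, "naive")
}

#' Mixed-model genome scan with fixed whitening
#'
#' Scans the genome under the QTL mixed model with the signal-to-noise ratio
#' held at its null-model estimate: for each marker the whitened design
#' `W = Sigma^(-1/2) X` is augmented with the whitened genotype column
#' `Sigma^(-1/2) q_m` and the whitened response is fitted by OLS, which is
#' the generalized-least-squares major-gene fit at `lambda = lam_hat`. The
#' t-statistic uses `nu = n_used - rank(W) - 1` and is mapped to a z-score.
#' Individuals with a missing genotype at a marker are dropped from the
#' whitened system for that marker (with the whitening of `q_m` restricted
#' to the retained rows); when `lam_hat = 0` the scan coincides exactly with
#' [naive_scan()].
#'
#' @inheritParams naive_scan
#' @param null_fit an `rcs_mixed_fit` from [fit_null_mixed()] computed on the
#'   same phenotypes.
#' @return a data frame of class `rcs_scan` (see [naive_scan()]).
#' @export
mixed_scan <- function(panel, phenotypes, null_fit,
                       variant = c("t", "tprime")) {
  variant <- match.arg(variant)
  .assert(inherits(panel, "rcs_panel"), "panel must be an rcs_panel")
  .assert(inherits(null_fit, "rcs_mixed_fit"),
          "null_fit must come from fit_null_mixed()")
  Q <- .individual_genotypes(panel, phenotypes)
  .assert(nrow(Q) == null_fit$n,
          "null_fit was computed on a different number of individuals")
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
  eng <- .scan_engine(null_fit$W, matrix(null_fit$v), Q,
                      whiten = whiten, bw_sub = bw_sub, variant = variant)
  .scan_result(panel$map, eng, variant, "mixed")
}

#' @export
print.rcs_scan <- function(x, ...) {
  cat(sprintf("%s genome scan (%s statistic): %d markers, %d skipped\n",
              attr(x, "model"), attr(x, "variant"), nrow(x), sum(x$skipped)))
  top <- x[!x$skipped, ]
  top <- top[order(-top$z)[seq_len(min(5, nrow(top)))], ]
  print.data.frame(top, row.names = FALSE, digits = 4)
  invisible(x)
}
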