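# Shared fixtures: a small panel for unit tests and the incidence helper.

tiny_map <- function(n_chr = 2, n_markers = 20, spacing = 5) {
  make_map(n_chr, n_markers, spacing)
}

tiny_panel <- function(n_strains = 8, seed = 101, ...) {
  simulate_rcs_panel(n_strains, tiny_map(...), seed = seed)
}

strain_incidence <- function(phenotypes, panel) {
  idx <- match(phenotypes$strain_id, panel$strain_id)
  Z <- matrix(0, nrow(phenotypes), length(panel$strain_id))
  Z[cbind(seq_len(nrow(phenotypes)), idx)] <- 1
  Z
}

# Independent profile-REML oracle: for a fixed lambda computes the exact GLS
# beta via a dense solve, and maximizes the restricted log-likelihood over
# lambda by one-dimensional search. Shares no code with the package's
# iterative moment estimator.
reml_oracle <- function(y, Z, K, interval = c(1e-6, 10)) {
  n <- length(y)
  X <- matrix(1, n, 1)
  A <- Z %*% as.matrix(K) %*% t(Z)
  restricted_ll <- function(lam) {
    Sig <- lam * A + diag(n)
    ch <- chol(Sig)
    Si_y <- backsolve(ch, forwardsolve(t(ch), y))
    Si_X <- backsolve(ch, forwardsolve(t(ch), X))
    XtSiX <- crossprod(X, Si_X)
    beta <- solve(XtSiX, crossprod(Si_X, y))
    r <- y - X %*% beta
    Si_r <- backsolve(ch, forwardsolve(t(ch), r))
    s2 <- sum(r * Si_r) / (n - ncol(X))
    -0.5 * (2 * sum(log(diag(ch))) + log(det(XtSiX)) +
              (n - ncol(X)) * log(s2))
  }
  lam <- stats::optimize(restricted_ll, interval, maximum = TRUE)$maximum
  Sig <- lam * A + diag(n)
  beta <- drop(solve(crossprod(X, solve(Sig, X)),
                     crossprod(X, solve(Sig, y))))
  list(lambda = lam, beta = beta)
}
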