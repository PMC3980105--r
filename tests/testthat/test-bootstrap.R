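# Leverage-adjusted residuals, pseudo-observations and the max-statistic
# bootstrap.

test_that("leverages are 1/n for a balanced intercept-only null model", {
  panel <- tiny_panel(n_strains = 6, seed = 91)
  K <- genomic_kinship(panel)
  Z <- kronecker(diag(6), matrix(1, 4, 1))
  set.seed(91)
  fit <- fit_mixed_given_lambda(rnorm(24, 7), NULL, Z, K, 0)
  res <- leverage_adjusted_residuals(fit)
  expect_equal(res$leverages, rep(1 / 24, 24))
  expect_equal(sum(res$leverages), fit$rank_W, tolerance = 1e-8)
})

test_that("leverages sum to the whitened design rank on random designs", {
  set.seed(92)
  panel <- tiny_panel(n_strains = 6, seed = 92)
  K <- genomic_kinship(panel)
  Z <- kronecker(diag(6), matrix(1, 5, 1))
  for (i in 1:5) {
    X <- cbind(1, matrix(rnorm(60), 30))
    fit <- fit_mixed_given_lambda(rnorm(30, 7), X, Z, K, runif(1, 0, 2))
    res <- leverage_adjusted_residuals(fit)
    expect_lt(abs(sum(res$leverages) - fit$rank_W), 1e-8)
    expect_true(all(res$leverages >= 0 & res$leverages < 1))
  }
})

test_that("the two leverage exponents differ by the documented factor", {
  panel <- tiny_panel(n_strains = 6, seed = 93)
  K <- genomic_kinship(panel)
  Z <- kronecker(diag(6), matrix(1, 4, 1))
  set.seed(93)
  fit <- fit_mixed_given_lambda(rnorm(24, 7), cbind(1, rnorm(24)), Z, K, 1)
  half <- leverage_adjusted_residuals(fit, "half", center = FALSE)
  one <- leverage_adjusted_residuals(fit, "one", center = FALSE)
  expect_equal(one$eps_tilde / half$eps_tilde,
               (1 - half$leverages)^(-1 / 2))
})

test_that("pseudo-observations center on the fitted whitened mean", {
  panel <- tiny_panel(n_strains = 6, seed = 94)
  K <- genomic_kinship(panel)
  Z <- kronecker(diag(6), matrix(1, 4, 1))
  set.seed(94)
  fit <- fit_mixed_given_lambda(rnorm(24, 7), NULL, Z, K, 0.5)
  res <- leverage_adjusted_residuals(fit)

  # fixed seed: identical draws
  expect_identical(draw_pseudo_observations(fit, res, seed = 7),
                   draw_pseudo_observations(fit, res, seed = 7))

  # degenerate residuals: v* equals the mean exactly
  res0 <- res
  res0$eps_tilde <- rep(0, 24)
  expect_equal(draw_pseudo_observations(fit, res0, seed = 1),
               drop(fit$W %*% fit$beta_hat))

  # Monte Carlo mean converges to W beta
  draws <- vapply(1:3000, function(i) draw_pseudo_observations(fit, res, seed = i),
                  numeric(24))
  mu <- drop(fit$W %*% fit$beta_hat)
  se <- sd(res$eps_tilde) / sqrt(3000)
  expect_true(all(abs(rowMeans(draws) - mu) < 4 * se))
})

test_that("bootstrap p-values are exact acceptance fractions", {
  panel <- tiny_panel(n_strains = 8, seed = 95)
  K <- genomic_kinship(panel)
  ph <- simulate_phenotypes(panel, K, n_per_strain = 3, lambda = 0, seed = 96)
  bt <- naive_bootstrap(panel, ph, R = 53, seed = 97)
  keep <- !bt$markers$skipped
  expect_equal(bt$markers$p[keep], bt$markers$count[keep] / 53)
  expect_true(all(bt$markers$p[keep] >= 0 & bt$markers$p[keep] <= 1))
  # single resample: p in {0, 1}
  b1 <- naive_bootstrap(panel, ph, R = 1, seed = 98)
  expect_true(all(b1$markers$p[!b1$markers$skipped] %in% c(0, 1)))
})

test_that("a zero-z marker is never more extreme than a resampled maximum", {
  panel <- tiny_panel(n_strains = 8, seed = 99)
  K <- genomic_kinship(panel)
  ph <- simulate_phenotypes(panel, K, n_per_strain = 3, lambda = 0, seed = 100)
  bt <- naive_bootstrap(panel, ph, R = 200, seed = 101)
  expect_true(all(bt$z_max_draws > 0))
  low <- which(!bt$markers$skipped & bt$markers$z == min(bt$markers$z))
  if (any(bt$markers$z[low] == 0)) {
    expect_equal(bt$markers$p[low], rep(1, length(low)))
  }
})

test_that("p-values are monotone decreasing in z within one bootstrap", {
  panel <- tiny_panel(n_strains = 10, seed = 102)
  K <- genomic_kinship(panel)
  ph <- simulate_phenotypes(panel, K, n_per_strain = 3, lambda = 1, seed = 103)
  for (bt in list(naive_bootstrap(panel, ph, R = 300, seed = 104),
                  mixed_bootstrap(panel, ph, K, R = 300, seed = 104))) {
    mk <- bt$markers[!bt$markers$skipped, ]
    ord <- order(mk$z)
    expect_true(all(diff(mk$p[ord]) <= 0))
  }
})

test_that("naive and mixed bootstrap coincide when lambda is 0 and kinship identity", {
  panel <- tiny_panel(n_strains = 10, seed = 105)
  Ki <- diag(10)
  dimnames(Ki) <- list(panel$strain_id, panel$strain_id)
  ph <- simulate_phenotypes(panel, Ki, n_per_strain = 3, lambda = 0,
                            seed = 106)
  Z <- strain_incidence(ph, panel)
  fit0 <- fit_mixed_given_lambda(ph$y, NULL, Z, Ki, 0)
  sn <- naive_scan(panel, ph)
  sm <- mixed_scan(panel, ph, fit0)
  expect_equal(as.data.frame(sm), as.data.frame(sn), ignore_attr = TRUE)

  bn <- naive_bootstrap(panel, ph, R = 400, seed = 107)
  bm <- mixed_bootstrap(panel, ph, Ki, R = 400, seed = 107, null_fit = fit0)
  # the same resampling index stream drives both, and the t statistic is
  # invariant under the affine map relating raw and residual resamples
  expect_equal(bm$markers$count, bn$markers$count)
  expect_equal(bm$markers$p, bn$markers$p)
  expect_equal(bm$z_max_draws, bn$z_max_draws, tolerance = 1e-10)
})

test_that("bootstrap results are reproducible and chunk-size invariant", {
  panel <- tiny_panel(n_strains = 8, seed = 108)
  K <- genomic_kinship(panel)
  ph <- simulate_phenotypes(panel, K, n_per_strain = 3, lambda = 0.5,
                            seed = 109)
  b1 <- naive_bootstrap(panel, ph, R = 150, seed = 110)
  b2 <- naive_bootstrap(panel, ph, R = 150, seed = 110)
  expect_identical(b1$markers$p, b2$markers$p)
})

test_that("peak counting respects chromosome boundaries and runs", {
  mk <- data.frame(
    marker = paste0("m", 1:8),
    chromosome = c(1, 1, 1, 1, 1, 2, 2, 2),
    position = c(0, 5, 10, 15, 20, 0, 5, 10),
    p = c(0.5, 0.001, 0.002, 0.9, 0.004, 0.003, 0.5, 0.2))
  # all above threshold: no peaks
  expect_equal(nrow(count_significant_peaks(
    transform(mk, p = pmax(p, 0.2)), 0.01)), 0)
  # one contiguous run: a single peak at its minimum
  one_run <- transform(mk, p = c(0.5, 0.001, 0.002, 0.9, 0.9, 0.9, 0.5, 0.2))
  pk <- count_significant_peaks(one_run, 0.01)
  expect_equal(pk$marker, "m2")
  # two runs on chromosome 1 separated by a supra-threshold marker, plus one
  # on chromosome 2 starting at its first marker
  pk2 <- count_significant_peaks(mk, 0.01)
  expect_equal(pk2$marker, c("m2", "m5", "m6"))
})

test_that("an all-skipped scan refuses to bootstrap", {
  map <- genetic_map(c("m1", "m2"), c(1, 1), c(0, 5))
  geno <- matrix(c(1L, 1L, 1L, 1L), 2)  # monomorphic everywhere
  panel <- rcs_panel(c("s1", "s2"), geno, map)
  ph <- data.frame(individual_id = paste0("i", 1:4),
                   strain_id = rep(c("s1", "s2"), each = 2),
                   y = c(1, 2, 3, 4))
  expect_error(naive_bootstrap(panel, ph, R = 10, seed = 1), "skipped")
})
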