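# Per-marker statistics: the t-to-z transform, the naive OLS scan and the
# whitened mixed-model scan.

test_that("t_to_z matches its closed form and limits", {
  expect_equal(t_to_z(0, 1), 0)
  expect_equal(t_to_z(0, 1e6), 0)
  expect_lt(abs(t_to_z(1.5, 1e9) - 1.5), 1e-6)
  expect_equal(t_to_z(2, 10), 2 * (1 - 1 / 40) / sqrt(1.2), tolerance = 1e-12)
  expect_equal(t_to_z(2, 10), 1.78010, tolerance = 1e-4)
  # t = Inf maps to the finite ceiling sqrt(2 nu) (1 - 1/(4 nu))
  expect_equal(t_to_z(Inf, 10), sqrt(20) * (1 - 1 / 40))
  expect_error(t_to_z(1, 0.5), "degrees of freedom")
})

test_that("z is increasing in t and in nu", {
  ts <- seq(0.1, 10, length.out = 40)
  for (nu in c(2, 5, 30, 200)) {
    expect_true(all(diff(t_to_z(ts, nu)) > 0))
  }
  nus <- c(1, 2, 5, 10, 50, 1000)
  for (t in c(0.5, 2, 8)) {
    expect_true(all(diff(t_to_z(rep(t, length(nus)), nus)) > 0))
  }
})

test_that("naive scan reproduces the textbook OLS t-test on toy data", {
  map <- genetic_map("m1", 1, 0)
  panel <- rcs_panel(paste0("s", 1:6), matrix(c(0L, 0L, 0L, 1L, 1L, 1L), 6),
                     map)
  ph <- data.frame(individual_id = paste0("i", 1:6),
                   strain_id = paste0("s", 1:6),
                   y = c(1, 2, 3, 7, 8, 9))
  sc <- naive_scan(panel, ph)
  expect_equal(sc$xi_hat, 6)
  ols <- summary(lm(y ~ q, data = data.frame(y = ph$y, q = c(0, 0, 0, 1, 1, 1))))
  expect_equal(sc$t, abs(ols$coefficients["q", "t value"]))
  expect_equal(sc$se, ols$coefficients["q", "Std. Error"], ignore_attr = TRUE)
  expect_equal(sc$nu, 4)
  expect_equal(sc$z, t_to_z(sc$t, 4))
})

test_that("a constant phenotype yields zero statistics at polymorphic markers", {
  panel <- tiny_panel(n_strains = 10, seed = 71)
  ph <- data.frame(individual_id = paste0("i", 1:20),
                   strain_id = rep(panel$strain_id, each = 2), y = rep(7, 20))
  sc <- naive_scan(panel, ph)
  expect_true(all(sc$xi_hat[!sc$skipped] == 0))
  expect_true(all(sc$t[!sc$skipped] == 0))
  expect_true(all(sc$z[!sc$skipped] == 0))
})

test_that("missing strain genotypes reduce the per-marker sample size", {
  panel <- tiny_panel(n_strains = 10, seed = 72)
  panel$genotypes[c(1, 2), 5] <- NA  # two strains missing at marker 5
  n_per <- 3
  K <- genomic_kinship(panel)
  ph <- simulate_phenotypes(panel, K, n_per_strain = n_per, lambda = 0,
                            seed = 73)
  sc <- naive_scan(panel, ph)
  expect_equal(sc$n_used[5], 30 - 2 * n_per)
  expect_equal(sc$nu[5], sc$nu[1] - 2 * n_per)
})

test_that("the mixed scan at lambda 0 equals the naive scan", {
  panel <- tiny_panel(n_strains = 8, seed = 74)
  panel$genotypes[1, 3] <- NA
  K <- genomic_kinship(panel)
  ph <- simulate_phenotypes(panel, K, n_per_strain = 3, lambda = 0, seed = 75)
  Z <- strain_incidence(ph, panel)
  fit0 <- fit_mixed_given_lambda(ph$y, NULL, Z, K, 0)
  for (variant in c("t", "tprime")) {
    sn <- naive_scan(panel, ph, variant = variant)
    sm <- mixed_scan(panel, ph, fit0, variant = variant)
    expect_equal(as.data.frame(sm), as.data.frame(sn), ignore_attr = TRUE)
  }
})

test_that("scans are invariant to marker order and strain relabeling", {
  panel <- tiny_panel(n_strains = 8, seed = 76)
  K <- genomic_kinship(panel)
  ph <- simulate_phenotypes(panel, K, n_per_strain = 3, lambda = 0.5,
                            seed = 77)
  sc <- naive_scan(panel, ph)

  # permute markers (within the map ordering constraint, permute chromosomes'
  # blocks by reversing chromosome order)
  ord <- order(match(panel$map$chromosome, rev(unique(panel$map$chromosome))),
               panel$map$position)
  panel2 <- rcs_panel(panel$strain_id, panel$genotypes[, ord],
                      genetic_map(panel$map$marker[ord],
                                  panel$map$chromosome[ord],
                                  panel$map$position[ord]),
                      panel$background_group, panel$donor_allele)
  sc2 <- naive_scan(panel2, ph)
  expect_equal(sc2$z, sc$z[ord])

  # relabel/permute strains
  perm <- c(3, 1, 2, 8, 7, 4, 5, 6)
  panel3 <- rcs_panel(panel$strain_id[perm], panel$genotypes[perm, ],
                      panel$map, panel$background_group[perm],
                      panel$donor_allele[perm])
  sc3 <- naive_scan(panel3, ph)
  expect_equal(sc3$z, sc$z)
})

test_that("z and t rank markers identically when degrees of freedom are constant", {
  panel <- tiny_panel(n_strains = 12, seed = 78)
  K <- genomic_kinship(panel)
  ph <- simulate_phenotypes(panel, K, n_per_strain = 3, lambda = 0.5,
                            seed = 79)
  sc <- naive_scan(panel, ph)
  keep <- !sc$skipped
  expect_equal(length(unique(sc$nu[keep])), 1)
  expect_equal(rank(sc$z[keep]), rank(sc$t[keep]))
})

test_that("the mixed scan localizes a planted QTL", {
  panel <- simulate_rcs_panel(36, make_map(19, 619, 3), seed = 80)
  K <- genomic_kinship(panel)
  Z <- kronecker(diag(36), matrix(1, 7, 1))
  cm <- colMeans(panel$genotypes)
  qtl <- panel$map$marker[which.min(abs(cm - 0.5))]
  qtl_row <- match(qtl, panel$map$marker)
  hits <- vapply(1:100, function(i) {
    ph <- simulate_phenotypes(panel, K, lambda = 1, xi = 3, qtl_marker = qtl,
                              seed = 800 + i)
    fit <- suppressWarnings(fit_null_mixed(ph$y, NULL, Z, K,
                                           keep_sigma = FALSE))
    sc <- mixed_scan(panel, ph, fit)
    top <- which.max(ifelse(sc$skipped, -Inf, sc$z))
    sc$chromosome[top] == sc$chromosome[qtl_row] &&
      abs(sc$position[top] - sc$position[qtl_row]) <= 5
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("the whitened residual variance is consistent on the whitened scale", {
  panel <- simulate_rcs_panel(24, make_map(5, 60, 4), seed = 81)
  K <- genomic_kinship(panel)
  Z <- kronecker(diag(24), matrix(1, 4, 1))
  s2 <- vapply(1:200, function(i) {
    ph <- simulate_phenotypes(panel, K, n_per_strain = 4, sigma2 = 1,
                              lambda = 1, seed = 8100 + i)
    fit_mixed_given_lambda(ph$y, NULL, Z, K, 1)$sigma2_hat
  }, numeric(1))
  # var of s2 ~ 2/(n - 1) on the whitened scale with sigma2 = 1
  expect_lt(abs(mean(s2) - 1), 3 * sqrt(2 / (96 - 1) / 200))
})
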