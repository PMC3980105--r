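# Individual-level phenotype simulation under the RCS/QTL mixed model
#   y = mu 1 + Z gamma + q_m xi + e,
# gamma ~ N(0, sigma2 * lambda * K) at strain level, e ~ N(0, sigma2 I).

#' Simulate phenotypes under the RCS mixed model
#'
#' Draws `n_per_strain` individuals per strain with phenotype
#' `y = mu + Z gamma + q xi + e`, where `gamma` is a strain-level polygenic
#' effect with covariance `sigma2 * lambda * K` (sampled through the
#' symmetric eigenvalue square root of `K`, so strain ordering does not
#' affect the distribution), `e` is iid `N(0, sigma2)`, and `q` is the
#' indicator of the recipient-homozygote (BB) genotype at `qtl_marker`.
#' Individuals inherit the genotype of their strain. The signal-to-noise
#' ratio `lambda = sigma2_g / sigma2` controls the strength of the polygenic
#' background; under a purely polygenic model it is monotone in heritability.
#'
#' The random draws are taken in a fixed order (first the S strain effects,
#' then the n individual errors) regardless of `lambda`, so phenotype sets
#' generated with the same seed at different `lambda` share the same
#' underlying noise realizations.
#'
#' @param panel an `rcs_panel`.
#' @param kinship an S x S positive-definite kinship matrix
#'   (see [genomic_kinship()], [expected_kinship()]).
#' @param n_per_strain individuals sampled per strain.
#' @param mu intercept (trait units).
#' @param sigma2 error variance, > 0.
#' @param lambda signal-to-noise ratio `sigma2_g / sigma2`, >= 0.
#' @param xi major-gene effect (trait units); requires `qtl_marker`.
#' @param qtl_marker marker identifier carrying the major gene, or `NULL`.
#' @param seed integer seed.
#' @return a data frame of class `rcs_phenotypes` with columns
#'   `individual_id`, `strain_id`, `y`.
#' @examples
#' panel <- simulate_rcs_panel(8, make_map(2, 30, 5), seed = 1)
#' ph <- simulate_phenotypes(panel, genomic_kinship(panel), n_per_strain = 3,
#'                           lambda = 1, seed = 2)
#' head(ph)
#' @export
simulate_phenotypes <- function(panel, kinship, n_per_strain = 7, mu = 7,
                                sigma2 = 1.175, lambda = 0, xi = 0,
                                qtl_marker = NULL, seed = NULL) {
  .assert(inherits(panel, "rcs_panel"), "panel must be an rcs_panel")
  .assert(sigma2 > 0, "sigma2 must be positive")
  .assert(lambda >= 0, "lambda must be non-negative")
  .assert(n_per_strain >= 1, "n_per_strain must be positive")
  if (xi != 0) .assert(!is.null(qtl_marker), "xi != 0 requires a qtl_marker")
  S <- length(panel$strain_id)
  kinship <- as.matrix(kinship)
  .assert(all(dim(kinship) == S), "kinship dimensions must match the panel")
  ev <- eigen((kinship + t(kinship)) / 2, symmetric = TRUE)
  if (min(ev$values) <= 0) {
    stop("kinship matrix is not positive definite; add a small diagonal jitter",
         call. = FALSE)
  }
  k_sqrt <- ev$vectors %*% (t(ev$vectors) * sqrt(ev$values))

  q_strain <- rep(0, S)
  if (!is.null(qtl_marker)) {
    col <- match(qtl_marker, panel$map$marker)
    .assert(!is.na(col), sprintf("qtl_marker '%s' is not on the map", qtl_marker))
    g <- panel$genotypes[, col]
    .assert(!anyNA(g), sprintf("marker '%s' has missing genotypes", qtl_marker))
    q_strain <- as.numeric(g == 1L)
  }

  if (!is.null(seed)) set.seed(seed)
  u <- stats::rnorm(S)
  gamma <- sqrt(sigma2 * lambda) * drop(k_sqrt %*% u)
  n <- S * n_per_strain
  e <- sqrt(sigma2) * stats::rnorm(n)
  strain_idx <- rep(seq_len(S), each = n_per_strain)
  y <- mu + gamma[strain_idx] + xi * q_strain[strain_idx] + e
  out <- data.frame(
    individual_id = sprintf("%s_i%d", panel$strain_id[strain_idx],
                            rep(seq_len(n_per_strain), S)),
    strain_id = panel$strain_id[strain_idx],
    y = y,
    stringsAsFactors = FALSE)
  class(out) <- c("rcs_phenotypes", "data.frame")
  out
}
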