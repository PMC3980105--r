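# Internal helpers shared across modules.

.assert <- function(ok, msg) {
  if (!isTRUE(ok)) stop(msg, call. = FALSE)
}

#' Moore-Penrose pseudoinverse
#'
#' Singular values below `rtol` times the largest are treated as zero.
#' Used for the generalized inverses (W'W)^- and (X'X)^- so that
#' rank-deficient designs are handled without special-casing.
#'
#' @param A numeric matrix.
#' @param rtol relative singular-value cutoff.
#' @return the pseudoinverse of `A`.
#' @keywords internal
#' @noRd
.pinv <- function(A, rtol = 1e-10) {
  s <- svd(A)
  keep <- s$d > rtol * max(s$d, 0)
  if (!any(keep)) {
    return(matrix(0, ncol(A), nrow(A)))
  }
  s$v[, keep, drop = FALSE] %*% (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

# All randomness flows from a single integer seed: a parent seed is expanded
# into child seeds with sample.int so that nested simulations are reproducible
# and independent streams do not overlap by construction of the generator.
.child_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(2147483646L, n)
}

# Strain-membership incidence matrix Z (n individuals x S strains), one unit
# entry per row.
.incidence <- function(strain_id, strain_levels) {
  idx <- match(strain_id, strain_levels)
  .assert(!anyNA(idx), "phenotypes reference strains absent from the panel")
  Z <- matrix(0, length(idx), length(strain_levels))
  Z[cbind(seq_along(idx), idx)] <- 1
  colnames(Z) <- strain_levels
  Z
}

# Individual-level genotype rows: every individual inherits the genotype of
# its strain (all animals within an RCS strain are genetically identical).
.individual_genotypes <- function(panel, phenotypes) {
  idx <- match(phenotypes$strain_id, panel$strain_id)
  .assert(!anyNA(idx), "phenotypes reference strains absent from the panel")
  panel$genotypes[idx, , drop = FALSE]
}
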