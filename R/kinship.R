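# Strain kinship matrices: the design-expectation form and the marker-based
# genomic estimate. Both are S x S, symmetric, with unit diagonal (up to an
# optional positive-definiteness jitter on the genomic estimate).

.new_kinship <- function(values, strain_id, method, jitter_applied = 0) {
  dimnames(values) <- list(strain_id, strain_id)
  structure(values, class = c("rcs_kinship", "matrix"),
            method = method, jitter = jitter_applied)
}

#' Expected kinship under the two-backcross RCS design
#'
#' The expected proportion of genome shared identical by descent between two
#' strains of a standard (two-backcross) RCS panel: 1 on the diagonal, 15/16
#' for distinct strains from the same background group, and 1/16 for strains
#' from different (reciprocal) backgrounds. These are exact rational design
#' expectations, not estimates.
#'
#' @param panel an `rcs_panel` with background-group labels.
#' @return an `rcs_kinship` matrix.
#' @examples
#' panel <- simulate_rcs_panel(6, make_map(1, 10, 5), seed = 1)
#' expected_kinship(panel)[1:3, 1:3]
#' @export
expected_kinship <- function(panel) {
  .assert(inherits(panel, "rcs_panel"), "panel must be an rcs_panel")
  g <- panel$background_group
  same <- outer(g, g, "==")
  K <- ifelse(same, 15 / 16, 1 / 16)
  diag(K) <- 1
  .new_kinship(K, panel$strain_id, method = "expected")
}

#' Genomic kinship estimate from marker sharing
#'
#' Entry (i, j) is the proportion of markers, among those with non-missing
#' genotypes in both strains, at which strains i and j carry the identical
#' parental-origin genotype. For fully inbred strains this is a direct
#' estimator of the identical-by-descent genome-sharing proportion. The
#' diagonal is forced to 1 and the result symmetrized. Elementwise division
#' by per-pair joint-observation counts can leave the matrix indefinite when
#' genotypes are missing; if the smallest eigenvalue is not positive, a
#' diagonal ridge of `jitter` plus the eigenvalue deficit is added (recorded
#' in the `"jitter"` attribute) so the matrix can serve as a covariance.
#'
#' @param panel an `rcs_panel`.
#' @param jitter base diagonal ridge, applied only when needed for positive
#'   definiteness.
#' @return an `rcs_kinship` matrix.
#' @export
genomic_kinship <- function(panel, jitter = 1e-6) {
  .assert(inherits(panel, "rcs_panel"), "panel must be an rcs_panel")
  .assert(jitter > 0, "jitter must be positive")
  g <- panel$genotypes
  obs <- !is.na(g)
  a <- (!is.na(g) & g == 0L) + 0
  b <- (!is.na(g) & g == 1L) + 0
  shared <- tcrossprod(a) + tcrossprod(b)
  joint <- tcrossprod(obs + 0)
  off <- joint == 0 & upper.tri(joint)
  if (any(off)) {
    idx <- which(off, arr.ind = TRUE)[1, ]
    stop(sprintf(
      "strains %s and %s have no jointly observed markers",
      panel$strain_id[idx[1]], panel$strain_id[idx[2]]), call. = FALSE)
  }
  K <- shared / joint
  K <- (K + t(K)) / 2
  diag(K) <- 1
  jit <- 0
  ev_min <- min(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min <= 1e-8) {
    jit <- jitter - min(ev_min, 0)
    K <- K + diag(jit, nrow(K))
  }
  .new_kinship(K, panel$strain_id, method = "genomic", jitter_applied = jit)
}

#' @export
print.rcs_kinship <- function(x, ...) {
  cat(sprintf("%s kinship matrix for %d strains", attr(x, "method"), nrow(x)))
  if (attr(x, "jitter") > 0) {
    cat(sprintf(" (ridge %g added for positive definiteness)", attr(x, "jitter")))
  }
  cat("\n")
  print(unclass(x)[seq_len(min(6, nrow(x))), seq_len(min(6, ncol(x)))])
  invisible(x)
}
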