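# RCS genotype panels: construction, simulation, missingness.
#
# Genotypes are stored as an S x M integer matrix with 0 = AA (homozygous for
# the first parental strain), 1 = BB (homozygous for the second parental
# strain) and NA = missing. RCS strains are fully inbred, so there are no
# heterozygotes. Each strain belongs to a background group; groups alternate
# the donor/recipient roles of the two parental strains (reciprocal sets), so
# a strain's own donor allele is "A" in odd-numbered groups and "B" in
# even-numbered groups.

#' Construct an RCS genotype panel
#'
#' @param strain_id character vector of unique strain identifiers.
#' @param genotypes S x M matrix with entries 0 (AA), 1 (BB) or NA (missing).
#' @param map a [genetic_map()] with M rows, in the column order of
#'   `genotypes`.
#' @param background_group integer vector of per-strain background-group
#'   labels.
#' @param donor_allele per-strain character vector, `"A"` or `"B"`: the
#'   genotype code corresponding to that strain's donor parental genome. If
#'   `NULL`, odd groups get `"A"` and even groups `"B"` (reciprocal sets).
#' @return an object of class `rcs_panel`.
#' @seealso [simulate_rcs_panel()], [read_panel()]
#' @export
rcs_panel <- function(strain_id, genotypes, map, background_group = 1L,
                      donor_allele = NULL) {
  strain_id <- as.character(strain_id)
  S <- length(strain_id)
  .assert(S >= 1, "panel must contain at least one strain")
  .assert(!anyDuplicated(strain_id), "strain identifiers must be unique")
  .assert(inherits(map, "genetic_map"), "map must be a genetic_map")
  genotypes <- as.matrix(genotypes)
  .assert(nrow(genotypes) == S, "genotype rows must match the strain count")
  .assert(ncol(genotypes) == nrow(map),
          "genotype columns must match the number of mapped markers")
  vals <- genotypes[!is.na(genotypes)]
  .assert(all(vals %in% c(0L, 1L)),
          "genotypes must be coded 0 (AA), 1 (BB) or NA")
  .assert(mean(is.na(genotypes)) < 1, "panel cannot be entirely missing")
  background_group <- rep_len(as.integer(background_group), S)
  if (is.null(donor_allele)) {
    donor_allele <- ifelse(background_group %% 2L == 1L, "A", "B")
  }
  donor_allele <- rep_len(as.character(donor_allele), S)
  .assert(all(donor_allele %in% c("A", "B")), "donor_allele must be 'A' or 'B'")
  storage.mode(genotypes) <- "integer"
  dimnames(genotypes) <- list(strain_id, map$marker)
  structure(list(strain_id = strain_id,
                 background_group = background_group,
                 donor_allele = donor_allele,
                 genotypes = genotypes,
                 map = map),
            class = "rcs_panel")
}

#' @export
print.rcs_panel <- function(x, ...) {
  cat(sprintf("RCS panel: %d strains x %d markers (%d chromosomes)\n",
              length(x$strain_id), ncol(x$genotypes),
              length(unique(x$map$chromosome))))
  cat(sprintf("  background groups: %s\n",
              paste(sort(unique(x$background_group)), collapse = ", ")))
  cat(sprintf("  missing genotypes: %.2f%%\n", 100 * mean(is.na(x$genotypes))))
  invisible(x)
}

#' Simulate a recombinant congenic strain panel
#'
#' Generates strain genotypes under a stationary two-state Markov chain along
#' each chromosome. The stationary probability of the donor (introgressed)
#' state is `donor_fraction` (1/8 for the standard two-backcross design), and
#' the dependence between adjacent markers decays with map distance: the
#' chain "refreshes" (redraws its state from the stationary distribution)
#' between markers at distance d Morgans with probability 1 - exp(-2 d
#' `expansion`), so the state autocorrelation is exp(-2 d `expansion`). The
#' `expansion` factor approximates the accumulated meioses of the breeding
#' scheme. Chromosomes and strains are independent.
#'
#' Strains are assigned round-robin to `n_background_groups` reciprocal
#' groups. Odd groups use parental strain B as recipient (donor allele "A"),
#' even groups swap the roles, so strains within one group share about
#' `1 - donor_fraction` of their genome through the common recipient while
#' strains in reciprocal groups share little.
#'
#' @param n_strains number of strains.
#' @param map a [genetic_map()].
#' @param n_background_groups number of reciprocal background groups.
#' @param donor_fraction stationary probability of the donor state, in (0, 1)
#'   (0 is allowed as a degenerate chain with no donor segments).
#' @param expansion meioses-equivalent scaling of map distances.
#' @param seed integer seed.
#' @return an `rcs_panel`.
#' @examples
#' panel <- simulate_rcs_panel(8, make_map(2, 40, 5), seed = 1)
#' mean(donor_genome_fraction(panel))  # close to 1/8
#' @export
simulate_rcs_panel <- function(n_strains, map, n_background_groups = 2,
                               donor_fraction = 1 / 8, expansion = 4,
                               seed = NULL) {
  .assert(inherits(map, "genetic_map"), "map must be a genetic_map")
  .assert(n_strains >= 1, "n_strains must be positive")
  .assert(n_background_groups >= 1 && n_background_groups <= n_strains,
          "need at least one strain per background group")
  .assert(donor_fraction >= 0 && donor_fraction < 1,
          "donor_fraction must lie in [0, 1)")
  .assert(expansion > 0, "expansion must be positive")
  if (!is.null(seed)) set.seed(seed)
  S <- n_strains
  M <- nrow(map)
  state <- matrix(0L, S, M)
  for (chr in unique(map$chromosome)) {
    cols <- which(map$chromosome == chr)
    d_morgan <- diff(map$position[cols]) / 100
    rho <- 1 - exp(-2 * d_morgan * expansion)
    state[, cols[1]] <- stats::rbinom(S, 1L, donor_fraction)
    if (length(cols) > 1) {
      for (k in seq_along(rho)) {
        refresh <- stats::runif(S) < rho[k]
        fresh <- stats::rbinom(S, 1L, donor_fraction)
        state[, cols[k + 1]] <- ifelse(refresh, fresh, state[, cols[k]])
      }
    }
  }
  group <- ((seq_len(S) - 1L) %% n_background_groups) + 1L
  # Odd groups: donor allele A, so donor state codes 0 (AA), background 1 (BB).
  # Even (reciprocal) groups: roles swapped.
  geno <- state
  odd <- group %% 2L == 1L
  geno[odd, ] <- 1L - state[odd, , drop = FALSE]
  rcs_panel(strain_id = sprintf("S%02d", seq_len(S)),
            genotypes = geno, map = map, background_group = group)
}

#' Per-strain donor genome fraction
#'
#' Fraction of (non-missing) markers at which a strain carries its own donor
#' parental genome; about 1/8 under the standard two-backcross RCS design.
#'
#' @param panel an `rcs_panel`.
#' @return named numeric vector, one entry per strain.
#' @export
donor_genome_fraction <- function(panel) {
  .assert(inherits(panel, "rcs_panel"), "panel must be an rcs_panel")
  donor_code <- ifelse(panel$donor_allele == "A", 0L, 1L)
  out <- vapply(seq_along(panel$strain_id), function(i) {
    g <- panel$genotypes[i, ]
    mean(g[!is.na(g)] == donor_code[i])
  }, numeric(1))
  names(out) <- panel$strain_id
  out
}

#' Set genotypes missing at random
#'
#' Each genotype call is independently replaced by NA with probability
#' `rate`; the map and strain labels are unchanged. Supports studying how
#' per-marker degrees of freedom vary with missing data.
#'
#' @param panel an `rcs_panel`.
#' @param rate missingness probability in \[0, 1).
#' @param seed integer seed.
#' @return an `rcs_panel` with additional missing entries.
#' @export
inject_missingness <- function(panel, rate, seed = NULL) {
  .assert(inherits(panel, "rcs_panel"), "panel must be an rcs_panel")
  .assert(is.numeric(rate) && length(rate) == 1 && rate >= 0 && rate < 1,
          "rate must lie in [0, 1)")
  if (rate == 0) return(panel)
  if (!is.null(seed)) set.seed(seed)
  g <- panel$genotypes
  drop <- matrix(stats::runif(length(g)) < rate, nrow(g), ncol(g))
  g[drop] <- NA_integer_
  panel$genotypes <- g
  panel
}
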