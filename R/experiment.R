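# Type-I-error simulation study: generate null datasets (polygenic
# background, no major gene) over a grid of signal-to-noise ratios, apply
# the naive and the mixed-model bootstrap, and tabulate the fraction of
# datasets declaring at least one significant peak genome-wide.

#' Configuration for a type-I-error study
#'
#' Defaults reproduce the study conditions: a 36-strain panel in two
#' reciprocal background groups, 619 markers over 19 autosomes at 3 cM
#' spacing, 7 individuals per strain, error variance 1.175, intercept 7,
#' signal-to-noise ratios {0, 1/8, 1/4, 1/2, 1, 2}, nominal genome-wide
#' level 0.01. `preset` scales the Monte Carlo effort: `"paper"` (1000
#' datasets x 10000 resamples), `"desk"` (200 x 1000), `"smoke"` (20 x 100).
#'
#' @param n_strains,n_chr,n_markers,spacing_cM,n_background_groups,
#'   donor_fraction,expansion panel dimensions, see [simulate_rcs_panel()].
#' @param n_per_strain individuals per strain.
#' @param lambdas signal-to-noise ratios to simulate.
#' @param sigma2 error variance (trait units squared).
#' @param mu intercept (trait units).
#' @param n_datasets simulated null datasets per lambda.
#' @param R bootstrap resamples per dataset.
#' @param alpha genome-wide significance level.
#' @param seed master seed; every random draw in the study derives from it.
#' @param preset `"paper"`, `"desk"`, `"smoke"` or `NULL` (use `n_datasets`
#'   and `R` as given).
#' @return a list of class `rcs_study_config`.
#' @export
study_config <- function(n_strains = 36, n_chr = 19, n_markers = 619,
                         spacing_cM = 3, n_background_groups = 2,
                         donor_fraction = 1 / 8, expansion = 4,
                         n_per_strain = 7,
                         lambdas = c(0, 1 / 8, 1 / 4, 1 / 2, 1, 2),
                         sigma2 = 1.175, mu = 7,
                         n_datasets = 1000, R = 10000, alpha = 0.01,
                         seed = 1, preset = NULL) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("paper", "desk", "smoke"))
    eff <- switch(preset,
                  paper = c(1000L, 10000L),
                  desk = c(200L, 1000L),
                  smoke = c(20L, 100L))
    n_datasets <- eff[1]
    R <- eff[2]
  }
  .assert(all(c(n_strains, n_chr, n_markers, n_per_strain, n_datasets, R) >= 1),
          "all counts must be positive")
  .assert(alpha > 0 && alpha < 1, "alpha must lie in (0, 1)")
  .assert(all(lambdas >= 0), "lambdas must be non-negative")
  .assert(sigma2 > 0, "sigma2 must be positive")
  structure(list(n_strains = n_strains, n_chr = n_chr, n_markers = n_markers,
                 spacing_cM = spacing_cM,
                 n_background_groups = n_background_groups,
                 donor_fraction = donor_fraction, expansion = expansion,
                 n_per_strain = n_per_strain, lambdas = lambdas,
                 sigma2 = sigma2, mu = mu, n_datasets = n_datasets, R = R,
                 alpha = alpha, seed = seed, preset = preset),
            class = "rcs_study_config")
}

#' Run the genome-wide type-I-error study
#'
#' Simulates one RCS panel from the master seed (held fixed across datasets,
#' as a real panel would be), computes its genomic kinship, then for each
#' signal-to-noise ratio simulates `n_datasets` null phenotype sets (no
#' major gene) and applies the requested bootstrap methodologies with `R`
#' resamples each. A dataset counts a genome-wide type I error when any
#' non-skipped marker reaches `p <= alpha` (equivalently, at least one
#' significant peak).
#'
#' Dataset-level seeds depend only on the dataset index, not on lambda or
#' the method, so the noise realizations are shared across arms (common
#' random numbers); each arm remains a valid marginal Monte Carlo estimate
#' while cross-arm comparisons (naive vs mixed, ordering in lambda) are
#' sharpened.
#'
#' @param config an [study_config()].
#' @param methods which methodologies to run.
#' @param verbose print per-arm progress?
#' @return an object of class `rcs_study`: `table` (one row per method x
#'   lambda with `type1`, its binomial `se`, `n_datasets`), `datasets`
#'   (per-dataset minimum genome-wide p and peak count), `panel`,
#'   `kinship`, `config`.
#' @export
run_type1_study <- function(config = study_config(),
                            methods = c("naive", "mixed"),
                            verbose = FALSE) {
  .assert(inherits(config, "rcs_study_config"), "config must be a study_config")
  methods <- match.arg(methods, c("naive", "mixed"), several.ok = TRUE)
  seeds <- .child_seeds(config$seed, 1L + 2L * config$n_datasets)
  panel_seed <- seeds[1]
  phen_seeds <- seeds[1 + seq_len(config$n_datasets)]
  boot_seeds <- seeds[1 + config$n_datasets + seq_len(config$n_datasets)]

  map <- make_map(config$n_chr, config$n_markers, config$spacing_cM)
  panel <- simulate_rcs_panel(config$n_strains, map,
                              config$n_background_groups,
                              config$donor_fraction, config$expansion,
                              seed = panel_seed)
  kinship <- genomic_kinship(panel)

  rows <- list()
  per_ds <- list()
  for (lam in config$lambdas) {
    minp <- matrix(NA_real_, config$n_datasets, length(methods),
                   dimnames = list(NULL, methods))
    npk <- minp
    for (d in seq_len(config$n_datasets)) {
      ph <- simulate_phenotypes(panel, kinship,
                                n_per_strain = config$n_per_strain,
                                mu = config$mu, sigma2 = config$sigma2,
                                lambda = lam, seed = phen_seeds[d])
      for (meth in methods) {
        bt <- if (meth == "naive") {
          naive_bootstrap(panel, ph, R = config$R, seed = boot_seeds[d])
        } else {
          suppressWarnings(
            mixed_bootstrap(panel, ph, kinship, R = config$R,
                            seed = boot_seeds[d]))
        }
        pv <- bt$markers$p[!bt$markers$skipped]
        minp[d, meth] <- min(pv)
        npk[d, meth] <- nrow(count_significant_peaks(bt, config$alpha))
      }
    }
    for (meth in methods) {
      t1 <- mean(minp[, meth] <= config$alpha)
      rows[[length(rows) + 1]] <- data.frame(
        method = meth, lambda = lam, type1 = t1,
        se = sqrt(t1 * (1 - t1) / config$n_datasets),
        n_datasets = config$n_datasets, R = config$R,
        stringsAsFactors = FALSE)
      per_ds[[length(per_ds) + 1]] <- data.frame(
        method = meth, lambda = lam, dataset = seq_len(config$n_datasets),
        min_p = minp[, meth], n_peaks = npk[, meth],
        stringsAsFactors = FALSE)
    }
    if (verbose) {
      message(sprintf("lambda = %g done (%s)", lam,
                      paste(methods, collapse = ", ")))
    }
  }
  structure(list(table = do.call(rbind, rows),
                 datasets = do.call(rbind, per_ds),
                 panel = panel, kinship = kinship, config = config),
            class = "rcs_study")
}

#' @export
print.rcs_study <- function(x, ...) {
  cat(sprintf(
    "Genome-wide type-I-error study: %d datasets x %d resamples per lambda (alpha = %g)\n",
    x$config$n_datasets, x$config$R, x$config$alpha))
  print.data.frame(x$table, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Side-by-side p-value profile of both methodologies on one dataset
#'
#' @param naive_result,mixed_result `rcs_bootstrap` objects computed on the
#'   same dataset.
#' @param threshold genome-wide level whose `-log10` reference line is
#'   attached as the `"threshold_line"` attribute (0.01 maps to 2).
#' @return a data frame ordered by chromosome and position with per-marker
#'   `z`, `p` and `neglog10_p` for both methods.
#' @export
profile_report <- function(naive_result, mixed_result, threshold = 0.01) {
  .assert(inherits(naive_result, "rcs_bootstrap") &&
            inherits(mixed_result, "rcs_bootstrap"),
          "inputs must be rcs_bootstrap objects")
  a <- naive_result$markers
  b <- mixed_result$markers
  .assert(identical(a$marker, b$marker),
          "results must come from the same panel")
  out <- data.frame(
    marker = a$marker, chromosome = a$chromosome, position = a$position,
    z_naive = a$z, p_naive = a$p, neglog10_p_naive = a$neglog10_p,
    z_mixed = b$z, p_mixed = b$p, neglog10_p_mixed = b$neglog10_p,
    stringsAsFactors = FALSE)
  out <- out[order(out$chromosome, out$position), ]
  rownames(out) <- NULL
  attr(out, "threshold_line") <- -log10(threshold)
  out
}

#' Write study outputs as plain-text tables
#'
#' Writes `type1_table.tsv` (method x lambda grid with binomial standard
#' errors), `peaks_table.tsv` (per-dataset peak counts and minimum p) and
#' `provenance.txt` (configuration and seed) under `dir`.
#'
#' @param study an `rcs_study`.
#' @param dir output directory (created if absent).
#' @return `study`, invisibly.
#' @export
write_study <- function(study, dir) {
  .assert(inherits(study, "rcs_study"), "study must be an rcs_study")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(study$table, file.path(dir, "type1_table.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(study$datasets, file.path(dir, "peaks_table.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- study$config
  writeLines(c(
    sprintf("%s = %s", names(unclass(cfg)),
            vapply(unclass(cfg), function(v)
              paste(format(v), collapse = " "), character(1))),
    sprintf("run_date = %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"))),
    file.path(dir, "provenance.txt"))
  invisible(study)
}
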