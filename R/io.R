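# Plain-text input/output. Genotype files are TSV with a header row
# "strain<TAB><marker ids>", one row per strain, cells in {A, B, NA}. Map
# files are TSV with columns marker_id, chromosome, position_cM. Kinship
# matrices are square CSV with strain ids on the first row and column.
# Phenotypes are TSV with columns individual_id, strain_id, y (plus optional
# covariates).

#' Read an RCS panel from genotype and map files
#'
#' @param genotype_path TSV file of genotype codes (header `strain` then one
#'   column per marker; cells `A`, `B` or `NA`).
#' @param map_path TSV file with columns `marker_id`, `chromosome`,
#'   `position_cM`.
#' @param strain_path optional TSV with columns `strain`,
#'   `background_group`, `donor_allele`; when absent all strains form one
#'   background group with donor allele `A`.
#' @return an `rcs_panel`.
#' @export
read_panel <- function(genotype_path, map_path, strain_path = NULL) {
  map_df <- utils::read.delim(map_path, stringsAsFactors = FALSE)
  .assert(all(c("marker_id", "chromosome", "position_cM") %in% names(map_df)),
          "map file must have columns marker_id, chromosome, position_cM")
  map <- genetic_map(map_df$marker_id, map_df$chromosome, map_df$position_cM)
  gt <- utils::read.delim(genotype_path, stringsAsFactors = FALSE,
                          colClasses = "character", check.names = FALSE,
                          na.strings = NULL)
  .assert(names(gt)[1] == "strain", "genotype file must start with a 'strain' column")
  gmark <- names(gt)[-1]
  missing_in_geno <- setdiff(map$marker, gmark)
  extra_in_geno <- setdiff(gmark, map$marker)
  if (length(missing_in_geno) || length(extra_in_geno)) {
    stop(sprintf(
      "map/genotype marker mismatch: %s",
      paste(c(missing_in_geno, extra_in_geno), collapse = ", ")), call. = FALSE)
  }
  codes <- as.matrix(gt[, map$marker, drop = FALSE])
  bad <- !(codes %in% c("A", "B", "NA"))
  if (any(bad)) {
    idx <- which(matrix(bad, nrow(codes)), arr.ind = TRUE)[1, ]
    stop(sprintf(
      "unknown genotype code '%s' at strain %s, marker %s",
      codes[idx[1], idx[2]], gt$strain[idx[1]], map$marker[idx[2]]),
      call. = FALSE)
  }
  geno <- matrix(NA_integer_, nrow(codes), ncol(codes))
  geno[codes == "A"] <- 0L
  geno[codes == "B"] <- 1L
  group <- 1L
  donor <- NULL
  if (!is.null(strain_path)) {
    sm <- utils::read.delim(strain_path, stringsAsFactors = FALSE)
    idx <- match(gt$strain, sm$strain)
    .assert(!anyNA(idx), "strain metadata file does not cover all strains")
    group <- as.integer(sm$background_group[idx])
    if ("donor_allele" %in% names(sm)) donor <- sm$donor_allele[idx]
  }
  rcs_panel(gt$strain, geno, map, background_group = group,
            donor_allele = donor)
}

#' Write an RCS panel to genotype, map and strain-metadata files
#'
#' Writing then reading the three files reproduces the panel exactly,
#' including missing entries.
#'
#' @param panel an `rcs_panel`.
#' @inheritParams read_panel
#' @return the panel, invisibly.
#' @export
write_panel <- function(panel, genotype_path, map_path, strain_path = NULL) {
  .assert(inherits(panel, "rcs_panel"), "panel must be an rcs_panel")
  codes <- matrix("NA", nrow(panel$genotypes), ncol(panel$genotypes))
  codes[!is.na(panel$genotypes) & panel$genotypes == 0L] <- "A"
  codes[!is.na(panel$genotypes) & panel$genotypes == 1L] <- "B"
  gt <- data.frame(strain = panel$strain_id, codes, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(gt) <- c("strain", panel$map$marker)
  utils::write.table(gt, genotype_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(
    data.frame(marker_id = panel$map$marker,
               chromosome = panel$map$chromosome,
               position_cM = panel$map$position),
    map_path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(strain_path)) {
    utils::write.table(
      data.frame(strain = panel$strain_id,
                 background_group = panel$background_group,
                 donor_allele = panel$donor_allele),
      strain_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(panel)
}

#' Read / write a kinship matrix as square CSV
#'
#' @param path CSV file; strain ids on the first row and column.
#' @return an `rcs_kinship` matrix.
#' @export
read_kinship <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, row.names = 1)
  K <- as.matrix(df)
  .assert(nrow(K) == ncol(K), "kinship file must be square")
  .assert(identical(rownames(K), colnames(K)),
          "kinship row and column ids must match")
  .new_kinship(K, rownames(K), method = "file")
}

#' @rdname read_kinship
#' @param kinship an `rcs_kinship` (or plain square matrix with dimnames).
#' @export
write_kinship <- function(kinship, path) {
  K <- as.matrix(kinship)
  utils::write.csv(data.frame(K, check.names = FALSE), path, quote = FALSE)
  invisible(kinship)
}

#' Read / write individual-level phenotypes as TSV
#'
#' @param path TSV file with columns `individual_id`, `strain_id`, `y` and
#'   any further covariate columns.
#' @return an `rcs_phenotypes` data frame.
#' @export
read_phenotypes <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  .assert(all(c("individual_id", "strain_id", "y") %in% names(df)),
          "phenotype file must have columns individual_id, strain_id, y")
  df$strain_id <- as.character(df$strain_id)
  class(df) <- c("rcs_phenotypes", "data.frame")
  df
}

#' @rdname read_phenotypes
#' @param phenotypes an `rcs_phenotypes` data frame.
#' @export
write_phenotypes <- function(phenotypes, path) {
  utils::write.table(as.data.frame(phenotypes), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(phenotypes)
}

#' Write per-marker scan or bootstrap tables as TSV
#'
#' For an `rcs_bootstrap`, a sidecar file `<path>.zmax` holding the R
#' resampled max statistics is written alongside.
#'
#' @param x an `rcs_scan` or `rcs_bootstrap`.
#' @param path output TSV path.
#' @return `x`, invisibly.
#' @export
write_scan <- function(x, path) {
  if (inherits(x, "rcs_bootstrap")) {
    utils::write.table(x$markers, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    writeLines(format(x$z_max_draws, digits = 10), paste0(path, ".zmax"))
  } else {
    utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(x)
}
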