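#' Construct a genetic map
#'
#' A genetic map is a data frame with one row per marker, giving the marker
#' identifier, its chromosome, and its position in centimorgans. Positions
#' must be strictly increasing within each chromosome and marker identifiers
#' must be unique.
#'
#' @param marker character vector of unique marker identifiers.
#' @param chromosome vector of chromosome labels, one per marker.
#' @param position numeric vector of map positions in centimorgans
#'   (non-negative, strictly increasing within each chromosome).
#' @return a data frame of class `genetic_map` with columns `marker`,
#'   `chromosome` and `position`.
#' @examples
#' genetic_map(c("m1", "m2", "m3"), c(1, 1, 2), c(0, 5, 0))
#' @export
genetic_map <- function(marker, chromosome, position) {
  marker <- as.character(marker)
  chromosome <- as.character(chromosome)
  position <- as.numeric(position)
  .assert(length(marker) > 0, "a genetic map must contain at least one marker")
  .assert(length(marker) == length(chromosome) &&
            length(marker) == length(position),
          "marker, chromosome and position must have equal length")
  .assert(!anyDuplicated(marker), "marker identifiers must be unique")
  .assert(all(is.finite(position)) && all(position >= 0),
          "map positions must be finite and non-negative")
  for (chr in unique(chromosome)) {
    p <- position[chromosome == chr]
    .assert(all(diff(p) > 0),
            sprintf("map positions must be strictly increasing within chromosome %s", chr))
  }
  out <- data.frame(marker = marker, chromosome = chromosome,
                    position = position, stringsAsFactors = FALSE)
  class(out) <- c("genetic_map", "data.frame")
  out
}

#' Build an evenly spaced genetic map
#'
#' Convenience constructor for simulation studies: `n_markers` markers are
#' spread over `n_chr` chromosomes as evenly as integer arithmetic allows,
#' with a constant inter-marker spacing on each chromosome.
#'
#' @param n_chr number of chromosomes.
#' @param n_markers total number of markers across the genome.
#' @param spacing_cM inter-marker distance in centimorgans.
#' @return a `genetic_map`. Markers are named `c<chr>m<index>`.
#' @examples
#' map <- make_map(n_chr = 19, n_markers = 619, spacing_cM = 3)
#' nrow(map)
#' @export
make_map <- function(n_chr = 19, n_markers = 619, spacing_cM = 3) {
  .assert(n_chr >= 1 && n_markers >= n_chr, "need at least one marker per chromosome")
  .assert(spacing_cM > 0, "spacing_cM must be positive")
  base <- n_markers %/% n_chr
  extra <- n_markers %% n_chr
  sizes <- rep(base, n_chr) + as.integer(seq_len(n_chr) <= extra)
  chr <- rep(seq_len(n_chr), sizes)
  within <- unlist(lapply(sizes, seq_len), use.names = FALSE)
  genetic_map(marker = sprintf("c%dm%d", chr, within),
              chromosome = chr,
              position = (within - 1) * spacing_cM)
}
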