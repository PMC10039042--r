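#' Construct a genome model
#'
#' A genome model is the spatial frame for arm-level scar logic: ordered
#' chromosome names with lengths and one centromere interval per
#' chromosome. Coordinates are 0-based half-open base pairs throughout the
#' package; readers convert from 1-based file conventions on input.
#'
#' @param chrom Character vector of unique chromosome names, in order.
#' @param length Chromosome lengths in bp (positive).
#' @param cen_start,cen_end Centromere interval per chromosome,
#'   0-based half-open, with `0 <= cen_start < cen_end <= length`.
#'
#' @return A tibble of class `genome_model` with columns `chrom`, `length`,
#'   `cen_start`, `cen_end`.
#' @examples
#' genome_model("chr1", 1e8, 4.9e7, 5.1e7)
#' @export
genome_model <- function(chrom, length, cen_start, cen_end) {
  if (anyDuplicated(chrom)) abort("genome_model: chromosome names must be unique")
  g <- tibble::tibble(
    chrom = as.character(chrom),
    length = as.numeric(length),
    cen_start = as.numeric(cen_start),
    cen_end = as.numeric(cen_end)
  )
  with(g, {
    if (any(length <= 0)) abort("genome_model: chromosome lengths must be > 0")
    if (any(cen_start < 0 | cen_start >= cen_end | cen_end > length)) {
      abort("genome_model: require 0 <= cen_start < cen_end <= length on every chromosome")
    }
  })
  class(g) <- c("genome_model", class(g))
  g
}

#' Deterministic toy genome for simulation and testing
#'
#' Builds a genome of `n_chrom` equal-length chromosomes named
#' `"chr1" ... "chrN"`, each with a centromere of width `cen_width_mb`
#' centred at `centromere_fraction` of the chromosome length. Two calls
#' with the same arguments return identical models.
#'
#' @param n_chrom Number of chromosomes (>= 1).
#' @param chrom_length_mb Chromosome length in megabases.
#' @param centromere_fraction Relative position of the centromere centre,
#'   strictly inside (0, 1). Default 0.5.
#' @param cen_width_mb Centromere width in megabases. Default 3.
#'
#' @return A `genome_model`.
#' @examples
#' make_toy_genome(3, 100)
#' @export
make_toy_genome <- function(n_chrom, chrom_length_mb,
                            centromere_fraction = 0.5, cen_width_mb = 3) {
  if (n_chrom < 1) abort("make_toy_genome: n_chrom must be >= 1")
  if (centromere_fraction <= 0 || centromere_fraction >= 1) {
    abort("make_toy_genome: centromere_fraction must lie strictly in (0, 1)")
  }
  len <- chrom_length_mb * 1e6
  half <- cen_width_mb * 1e6 / 2
  mid <- centromere_fraction * len
  cs <- max(0, mid - half)
  ce <- min(len, mid + half)
  genome_model(
    chrom = paste0("chr", seq_len(n_chrom)),
    length = rep(len, n_chrom),
    cen_start = rep(cs, n_chrom),
    cen_end = rep(ce, n_chrom)
  )
}
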