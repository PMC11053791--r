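#' Genome index: ordered chromosome names and lengths
#'
#' Minimal sequence dictionary shared by the simulator, the windowing code and
#' the VCF writer. Coordinates throughout the package are 1-based inclusive;
#' conversion to 0-based half-open happens only at the BED/bedGraph boundary.
#'
#' @param chrom character vector of unique chromosome names.
#' @param length integer vector of chromosome lengths in bp, all > 0.
#' @return a `genome_index` data.frame with columns `chrom`, `length`.
#' @export
#' @examples
#' genome_index(c("chr1", "chr2"), c(2e6, 2e6))
genome_index <- function(chrom, length) {
  chrom <- as.character(chrom)
  length <- as.numeric(length)
  if (anyDuplicated(chrom)) stopf("duplicate chromosome names")
  if (length(chrom) != base::length(length)) stopf("chrom and length differ in length")
  if (any(!is.finite(length)) || any(length <= 0)) stopf("chromosome lengths must be > 0")
  gi <- data.frame(chrom = chrom, length = length, stringsAsFactors = FALSE)
  class(gi) <- c("genome_index", "data.frame")
  gi
}

#' Default synthetic rice-like genome
#'
#' Twelve chromosomes, scaled down from rice (~2 Mb each by default) so that
#' whole-pipeline simulations run in seconds while keeping the 12-chromosome
#' layout of the real karyotype.
#'
#' @param chrom_length length of each chromosome in bp.
#' @param n_chrom number of chromosomes.
#' @return a [genome_index()].
#' @export
default_genome <- function(chrom_length = 2e6, n_chrom = 12) {
  genome_index(paste0("chr", seq_len(n_chrom)), rep(chrom_length, n_chrom))
}

#' @export
print.genome_index <- function(x, ...) {
  cat(sprintf("genome_index: %d chromosomes, %.3g bp total\n",
              nrow(x), sum(x$length)))
  NextMethod()
}
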