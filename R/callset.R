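INFO_KEYS <- c("QD", "MQ", "FS", "SOR", "MQRankSum", "ReadPosRankSum")
GT_STATES <- c("hom_ref", "het", "hom_alt", "missing")

#' Construct a call set
#'
#' One sample's variant calls against a named reference: a sorted table of
#' biallelic records. Multi-allelic sites are represented as one record per
#' alternate allele, so uniqueness is enforced on (chrom, pos, alt).
#'
#' @param sample_id sample name.
#' @param reference_name name of the common reference the calls are against.
#' @param records data.frame with columns `chrom`, `pos` (1-based), `ref`,
#'   `alt`, `genotype` (one of `"hom_ref"`, `"het"`, `"hom_alt"`,
#'   `"missing"`), plus any of the optional numeric quality-annotation columns
#'   `QD`, `MQ`, `FS`, `SOR`, `MQRankSum`, `ReadPosRankSum`.
#' @return a `callset` object.
#' @export
callset <- function(sample_id, reference_name, records) {
  rec <- data.table::as.data.table(records)
  needed <- c("chrom", "pos", "ref", "alt", "genotype")
  miss <- setdiff(needed, names(rec))
  if (length(miss)) stopf("records lack column(s): %s", paste(miss, collapse = ", "))
  rec[, chrom := as.character(chrom)]
  rec[, pos := as.numeric(pos)]
  rec[, ref := as.character(ref)]
  rec[, alt := as.character(alt)]
  rec[, genotype := as.character(genotype)]
  if (nrow(rec)) {
    if (any(rec$pos < 1)) stopf("positions must be >= 1")
    if (any(rec$ref == rec$alt)) stopf("ref and alt alleles must differ")
    bad <- setdiff(unique(rec$genotype), GT_STATES)
    if (length(bad)) stopf("unknown genotype state(s): %s", paste(bad, collapse = ", "))
    if (anyDuplicated(rec, by = c("chrom", "pos", "alt")))
      stopf("duplicate (chrom, pos, alt) records")
    if (!identical(order(rec$chrom, rec$pos), seq_len(nrow(rec)))) {
      data.table::setorder(rec, chrom, pos, alt)
    }
  }
  structure(
    list(sample_id = as.character(sample_id),
         reference_name = as.character(reference_name),
         records = rec),
    class = "callset"
  )
}

#' @export
print.callset <- function(x, ...) {
  cat(sprintf("callset '%s' vs reference '%s': %d records (%d SNPs) on %d chromosome(s)\n",
              x$sample_id, x$reference_name, nrow(x$records),
              sum(is_snp(x$records)), length(unique(x$records$chrom))))
  invisible(x)
}

#' @export
length.callset <- function(x) nrow(x$records)

# logical: which records are single-base substitutions
is_snp <- function(records) {
  nchar(records$ref) == 1L & nchar(records$alt) == 1L
}

#' Keep only SNP records of a call set
#'
#' Trio origin classification operates on SNPs; InDel records are the raw
#' material of marker design instead.
#'
#' @param cs a [callset()].
#' @return a `callset` containing the single-base substitution records.
#' @export
snps_only <- function(cs) {
  callset(cs$sample_id, cs$reference_name, cs$records[is_snp(cs$records)])
}

#' Keep only InDel records of a call set
#'
#' @param cs a [callset()].
#' @return a `callset` with the records whose ref/alt lengths differ.
#' @export
indels_only <- function(cs) {
  callset(cs$sample_id, cs$reference_name,
          cs$records[nchar(ref) != nchar(alt)])
}
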