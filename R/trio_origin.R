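ORIGIN_CATEGORIES <- c("donor", "receptor", "heterozygous", "unknown")

#' Classify an improved line's SNPs by parental origin
#'
#' For every SNP site where the improved line is non-reference, assigns one of
#' four mutually exclusive origin categories against the two parents:
#' \enumerate{
#'   \item improved line heterozygous at the site -> `heterozygous`;
#'   \item else, receptor parent homozygous for the same alternate allele ->
#'     `receptor`;
#'   \item else, donor homozygous for the same alternate allele -> `donor`;
#'   \item else -> `unknown` (allele seen in neither parent).
#' }
#' Receptor takes precedence over donor where both parents share the allele:
#' such sites are uninformative for introgression and belong to the shared
#' background. Sites absent from a parent call set are treated as homozygous
#' reference in that parent (`strict_missing = TRUE` instead drops sites whose
#' parent genotype is explicitly missing). Improved-line sites that are
#' homozygous reference or have missing genotype are excluded from the table.
#' Only single-base substitutions are classified; InDel records are ignored
#' here (they feed marker design instead).
#'
#' @param improved,donor,receptor [callset()]s against the same reference.
#' @param strict_missing drop sites whose parent genotype is recorded as
#'   missing instead of assuming homozygous reference.
#' @return a `trio_origin_table`: list with `sites` (chrom, pos, category),
#'   `summary` (per-category counts and percentages, see
#'   [summarize_percentages()]), `n_improved_snps` (classifiable input sites)
#'   and `n_excluded` (hom-ref/missing improved sites excluded).
#' @export
classify_trio <- function(improved, donor, receptor, strict_missing = FALSE) {
  for (cs in list(improved, donor, receptor)) stopifnot(inherits(cs, "callset"))
  refs <- c(improved$reference_name, donor$reference_name, receptor$reference_name)
  if (length(unique(refs)) != 1L)
    stopf("call sets are against different references: %s",
          paste(unique(refs), collapse = ", "))

  imp <- improved$records[is_snp(improved$records)]
  if (anyDuplicated(imp, by = c("chrom", "pos")))
    stopf("duplicate positions in improved call set")
  n_in <- nrow(imp)
  keep <- !imp$genotype %in% c("hom_ref", "missing")
  imp <- imp[keep, .(chrom, pos, alt, genotype)]

  don <- donor$records[is_snp(donor$records), .(chrom, pos, alt, gt_donor = genotype)]
  rec <- receptor$records[is_snp(receptor$records), .(chrom, pos, alt, gt_receptor = genotype)]

  # same-allele parent genotypes; absent rows = hom_ref by assumption
  imp <- don[imp, on = c("chrom", "pos", "alt")]
  imp <- rec[imp, on = c("chrom", "pos", "alt")]
  if (strict_missing) {
    drop <- (!is.na(imp$gt_donor) & imp$gt_donor == "missing") |
      (!is.na(imp$gt_receptor) & imp$gt_receptor == "missing")
    imp <- imp[!drop]
  }
  category <- data.table::fifelse(
    imp$genotype == "het", "heterozygous",
    data.table::fifelse(
      !is.na(imp$gt_receptor) & imp$gt_receptor == "hom_alt", "receptor",
      data.table::fifelse(
        !is.na(imp$gt_donor) & imp$gt_donor == "hom_alt", "donor", "unknown")))

  sites <- data.table::data.table(chrom = imp$chrom, pos = imp$pos,
                                  category = category)
  data.table::setorder(sites, chrom, pos)
  out <- structure(
    list(sites = sites, summary = NULL,
         n_improved_snps = n_in, n_excluded = n_in - nrow(sites)),
    class = "trio_origin_table")
  out$summary <- if (nrow(sites)) summarize_percentages(out) else
    data.frame(category = c(ORIGIN_CATEGORIES, "total"), count = 0L,
               percent = NA_real_, stringsAsFactors = FALSE)
  out
}

#' Per-category counts and percentages of an origin table
#'
#' Percentages are on the printed 0-100 scale, rounded half-up to two
#' decimals; counts always sum to the total.
#'
#' @param table a `trio_origin_table` from [classify_trio()], or a data.frame
#'   with a `category` column.
#' @return data.frame with one row per category (donor, receptor,
#'   heterozygous, unknown) plus a `total` row; columns category, count,
#'   percent.
#' @export
summarize_percentages <- function(table) {
  sites <- if (inherits(table, "trio_origin_table")) table$sites else table
  if (!nrow(sites)) stopf("empty origin table")
  counts <- vapply(ORIGIN_CATEGORIES,
                   function(k) sum(sites$category == k), 0L)
  total <- sum(counts)
  data.frame(
    category = c(ORIGIN_CATEGORIES, "total"),
    count = c(counts, total),
    percent = c(round_half_up(100 * counts / total, 2), 100),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' @export
print.trio_origin_table <- function(x, ...) {
  cat(sprintf("trio_origin_table: %d classified sites (%d excluded hom-ref/missing)\n",
              nrow(x$sites), x$n_excluded))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Write an origin table to TSV files
#'
#' @param table a `trio_origin_table`.
#' @param sites_path per-site TSV path (chrom, pos, category); NULL to skip.
#' @param summary_path summary TSV path; NULL to skip.
#' @return invisibly, the table.
#' @export
write_origin_table <- function(table, sites_path = NULL, summary_path = NULL) {
  if (!is.null(sites_path))
    data.table::fwrite(table$sites, sites_path, sep = "\t")
  if (!is.null(summary_path))
    utils::write.table(table$summary, summary_path, sep = "\t",
                       row.names = FALSE, quote = FALSE)
  invisible(table)
}

#' Read a per-site origin TSV back into a usable table
#'
#' @param path TSV with columns chrom, pos, category.
#' @return a `trio_origin_table` (summary recomputed).
#' @export
read_origin_table <- function(path) {
  sites <- data.table::fread(path)
  stopifnot(all(c("chrom", "pos", "category") %in% names(sites)))
  out <- structure(list(sites = sites[, .(chrom, pos, category)],
                        summary = NULL,
                        n_improved_snps = nrow(sites), n_excluded = 0L),
                   class = "trio_origin_table")
  out$summary <- summarize_percentages(out)
  out
}
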