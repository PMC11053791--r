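KASP_TAIL_FAM <- "GAAGGTGACCAAGTTCATGCT"
KASP_TAIL_HEX <- "GAAGGTCGGAGTCAACGGATT"

#' Annotate a coding-sequence SNP at the codon level
#'
#' Translates the reference and alternate codons under the standard genetic
#' code and classifies the effect. The codon number is `ceiling(pos / 3)`;
#' e.g. a G-to-A substitution at CDS position 1880 falls in codon 627 and, if
#' that codon is AGC (Ser), yields the S627N missense change.
#'
#' @param cds coding sequence (character, length divisible by 3, starting at
#'   the first codon).
#' @param pos 1-based position of the SNP within the CDS.
#' @param ref_base,alt_base reference and alternate bases; `ref_base` must
#'   match the CDS.
#' @return list with cds_pos, codon_number, pos_in_codon, ref_codon,
#'   alt_codon, ref_aa, alt_aa, effect (`synonymous`/`missense`/`nonsense`)
#'   and a protein-style `label` such as `"S627N"`.
#' @export
annotate_cds_variant <- function(cds, pos, ref_base, alt_base) {
  cds <- toupper(cds)
  if (nchar(cds) %% 3 != 0) stopf("CDS length %d is not divisible by 3", nchar(cds))
  if (pos < 1 || pos > nchar(cds)) stopf("pos outside CDS")
  obs <- substr(cds, pos, pos)
  if (obs != toupper(ref_base))
    stopf("reference base mismatch at CDS pos %d: expected %s, observed %s",
          pos, ref_base, obs)
  codon_number <- ceiling(pos / 3)
  pos_in_codon <- (pos - 1L) %% 3L + 1L
  cstart <- (codon_number - 1L) * 3L + 1L
  ref_codon <- substr(cds, cstart, cstart + 2L)
  alt_codon <- ref_codon
  substr(alt_codon, pos_in_codon, pos_in_codon) <- toupper(alt_base)
  code <- Biostrings::GENETIC_CODE
  ref_aa <- unname(code[ref_codon])
  alt_aa <- unname(code[alt_codon])
  effect <- if (alt_aa == ref_aa) "synonymous"
            else if (alt_aa == "*") "nonsense" else "missense"
  list(cds_pos = pos, codon_number = codon_number, pos_in_codon = pos_in_codon,
       ref_codon = ref_codon, alt_codon = alt_codon,
       ref_aa = ref_aa, alt_aa = alt_aa, effect = effect,
       label = sprintf("%s%d%s", ref_aa, codon_number, alt_aa))
}

#' Find InDels linked to a target locus
#'
#' Returns the InDel records of a donor-vs-reference call set lying within
#' `flank_bp` of the target position (closed interval) whose allele length
#' difference is within the gel-resolvable range, sorted by distance to the
#' target.
#'
#' @param cs a [callset()] of donor-vs-reference variants.
#' @param target_chrom,target_pos target locus.
#' @param flank_bp search radius in bp (> 0).
#' @param min_len,max_len allele length difference bounds (defaults
#'   20-80 bp: resolvable on a 2.5% agarose gel).
#' @return data.frame of qualifying InDel records with an extra `distance`
#'   column; empty when none qualify.
#' @export
find_linked_indels <- function(cs, target_chrom, target_pos, flank_bp,
                               min_len = 20, max_len = 80) {
  if (flank_bp <= 0) stopf("flank_bp must be > 0")
  rec <- cs$records
  d <- abs(nchar(rec$ref) - nchar(rec$alt))
  keep <- rec$chrom == target_chrom & d >= min_len & d <= max_len &
    rec$pos >= target_pos - flank_bp & rec$pos <= target_pos + flank_bp
  out <- rec[keep]
  out[, distance := abs(pos - target_pos)]
  data.table::setorder(out, distance)
  as.data.frame(out)
}

#' In-silico PCR on one template
#'
#' Finds the forward primer on the plus strand and the reverse primer as its
#' reverse complement on the template; a product requires exactly one binding
#' site for each, in amplifying orientation.
#'
#' @param template template sequence (character).
#' @param fwd,rev primer sequences 5'->3' (>= 15 bp).
#' @param max_mismatch allowed mismatches per primer site (default 0).
#' @return list with `status` (`"ok"`, `"no_fwd_site"`, `"no_rev_site"`,
#'   `"multiple_sites"`, `"wrong_orientation"`), and for `"ok"`: `start`,
#'   `end` (1-based product span), `length`, `product`.
#' @export
#' @examples
#' tpl <- paste0("ATGCATGCATGCATGCAT", strrep("G", 50), "TTTTAAAACCCCGGGGAA")
#' insilico_pcr(tpl, "ATGCATGCATGCATGC", "TTCCCCGGGGTTTTAA")$length
insilico_pcr <- function(template, fwd, rev, max_mismatch = 0) {
  if (nchar(fwd) < 15 || nchar(rev) < 15) stopf("primers must be >= 15 bp")
  tpl <- Biostrings::DNAString(template)
  f_hits <- Biostrings::matchPattern(Biostrings::DNAString(fwd), tpl,
                                     max.mismatch = max_mismatch)
  r_hits <- Biostrings::matchPattern(
    Biostrings::reverseComplement(Biostrings::DNAString(rev)), tpl,
    max.mismatch = max_mismatch)
  if (length(f_hits) == 0L) return(list(status = "no_fwd_site"))
  if (length(r_hits) == 0L) return(list(status = "no_rev_site"))
  if (length(f_hits) > 1L || length(r_hits) > 1L)
    return(list(status = "multiple_sites"))
  s <- BiocGenerics::start(f_hits)[1]
  e <- BiocGenerics::end(r_hits)[1]
  if (e <= s) return(list(status = "wrong_orientation"))
  list(status = "ok", start = s, end = e, length = e - s + 1L,
       product = substr(template, s, e))
}

# scan fixed-length primer windows for GC% range and single-site uniqueness
pick_primer <- function(template, positions, primer_len, gc_range = c(0.4, 0.6)) {
  best <- NULL; best_gc_dist <- Inf
  for (p in positions) {
    if (p < 1 || p + primer_len - 1 > nchar(template)) next
    cand <- substr(template, p, p + primer_len - 1)
    if (length(motif_matches(template, cand)) != 1L) next
    gc <- gc_fraction(cand)
    gc_dist <- max(0, gc_range[1] - gc, gc - gc_range[2])
    if (gc_dist == 0) return(list(seq = cand, start = p))
    if (gc_dist < best_gc_dist) { best <- list(seq = cand, start = p); best_gc_dist <- gc_dist }
  }
  best
}

#' Design a codominant InDel marker around a known InDel
#'
#' Picks a fixed-length forward primer upstream and reverse primer downstream
#' of an InDel on the reference-allele template (GC 40-60% and single-site
#' uniqueness preferred), then predicts product sizes on both alleles by
#' in-silico PCR. A candidate is returned only when the reference product is
#' inside `product_range` and the allele size difference (= the InDel length)
#' is within `diff_range`.
#'
#' @param ref_seq reference-allele template.
#' @param indel_start 1-based start of the deleted segment on `ref_seq`.
#' @param indel_len deletion length in bp (donor allele lacks these bases).
#' @param primer_len primer length (default 20).
#' @param product_range acceptable reference-allele product size (bp).
#' @param diff_range acceptable allele size difference (bp).
#' @return list (marker_type `"indel"`, primers, product_length_ref,
#'   product_length_alt) or NULL when no acceptable design exists.
#' @export
design_indel_marker <- function(ref_seq, indel_start, indel_len,
                                primer_len = 20, product_range = c(80, 300),
                                diff_range = c(20, 80)) {
  if (indel_len < diff_range[1] || indel_len > diff_range[2]) return(NULL)
  L <- nchar(ref_seq)
  fwd_starts <- seq(indel_start - primer_len, 1)
  fwd <- pick_primer(ref_seq, fwd_starts, primer_len)
  if (is.null(fwd)) return(NULL)
  rev_starts <- seq(indel_start + indel_len, L - primer_len + 1)
  rv <- NULL
  for (p in rev_starts) {
    prod_len <- p + primer_len - 1 - fwd$start + 1
    if (prod_len < product_range[1]) next
    if (prod_len > product_range[2]) break
    cand <- pick_primer(ref_seq, p, primer_len)
    if (!is.null(cand)) { rv <- cand; break }
  }
  if (is.null(rv)) return(NULL)
  rev_primer <- revcomp(rv$seq)
  p_ref <- insilico_pcr(ref_seq, fwd$seq, rev_primer)
  alt_seq <- paste0(substr(ref_seq, 1, indel_start - 1),
                    substr(ref_seq, indel_start + indel_len, L))
  p_alt <- insilico_pcr(alt_seq, fwd$seq, rev_primer)
  if (p_ref$status != "ok" || p_alt$status != "ok") return(NULL)
  list(marker_type = "indel",
       forward = fwd$seq, reverse = rev_primer,
       forward_start = fwd$start, reverse_end = rv$start + primer_len - 1,
       product_length_ref = p_ref$length, product_length_alt = p_alt$length,
       size_difference = p_ref$length - p_alt$length)
}

#' Design a CAPS marker for a SNP
#'
#' Given the two allele sequences around a SNP (identical except the SNP), a
#' candidate is returned iff some enzyme's recognition site overlaps the SNP
#' in exactly one allele, so digestion distinguishes the alleles. Fragment
#' predictions for both alleles are attached.
#'
#' @param ref_seq,alt_seq allele sequences, equal length, differing at
#'   exactly one position.
#' @param enzymes enzyme table as from [restriction_enzymes()].
#' @return list (marker_type `"caps"`, enzyme, motif, snp_pos, site_change
#'   `"gain"`/`"loss"` relative to the reference allele, fragments_ref,
#'   fragments_alt) or NULL when no enzyme discriminates.
#' @export
design_caps <- function(ref_seq, alt_seq, enzymes = restriction_enzymes()) {
  if (nchar(ref_seq) != nchar(alt_seq))
    stopf("allele sequences differ in length; CAPS design needs a SNP")
  diffs <- which(strsplit(ref_seq, "")[[1]] != strsplit(alt_seq, "")[[1]])
  if (length(diffs) != 1L)
    stopf("allele sequences must differ at exactly one position (found %d)",
          length(diffs))
  snp <- diffs
  for (i in seq_len(nrow(enzymes))) {
    k <- nchar(enzymes$motif[i])
    over <- function(seq) {
      s <- motif_matches(seq, enzymes$motif[i])
      sum(s <= snp & s + k - 1 >= snp)
    }
    n_ref <- over(ref_seq); n_alt <- over(alt_seq)
    if ((n_ref > 0) == (n_alt > 0)) next
    return(list(
      marker_type = "caps", enzyme = enzymes$name[i], motif = enzymes$motif[i],
      snp_pos = snp, site_change = if (n_ref > 0) "loss" else "gain",
      fragments_ref = insilico_digest(ref_seq, enzymes$name[i]),
      fragments_alt = insilico_digest(alt_seq, enzymes$name[i])))
  }
  NULL
}

#' Design a KASP primer set for a SNP
#'
#' Builds the two allele-specific forward primers ending exactly at the
#' variant base — identical except that 3'-terminal base (reference vs
#' alternate allele) — prepends the standard FAM and HEX tail sequences, and
#' picks a common reverse primer on the opposite strand within the requested
#' product-size range.
#'
#' @param flank_seq template sequence containing the variant.
#' @param variant_pos 1-based position of the variant in `flank_seq`.
#' @param ref_base,alt_base the two alleles at the variant.
#' @param allele_primer_len length of the allele-specific (untailed) forward
#'   primers; at least that much left flank is required.
#' @param rev_primer_len common reverse primer length.
#' @param product_range target product size range (tails excluded).
#' @return a `kasp_primer_set` list: allele1_forward / allele2_forward
#'   (tailed), common_reverse, tail1, tail2, untailed forwards, and the
#'   variant description.
#' @export
design_kasp <- function(flank_seq, variant_pos, ref_base, alt_base,
                        allele_primer_len = 25, rev_primer_len = 20,
                        product_range = c(50, 150)) {
  flank_seq <- toupper(flank_seq)
  L <- nchar(flank_seq)
  if (variant_pos < allele_primer_len || L - variant_pos < 25)
    stopf("flank too short: need >= %d bp upstream and >= 25 bp downstream of the variant",
          allele_primer_len)
  obs <- substr(flank_seq, variant_pos, variant_pos)
  if (obs != toupper(ref_base))
    stopf("reference base mismatch at variant position: expected %s, observed %s",
          ref_base, obs)
  core <- substr(flank_seq, variant_pos - allele_primer_len + 1, variant_pos - 1)
  fwd1 <- paste0(core, toupper(ref_base))
  fwd2 <- paste0(core, toupper(alt_base))

  p_start <- variant_pos - allele_primer_len + 1
  rv <- NULL
  for (prod_len in seq(product_range[1], product_range[2])) {
    p <- p_start + prod_len - rev_primer_len
    if (p <= variant_pos) next               # reverse site must sit 3' of the variant
    if (p + rev_primer_len - 1 > L) break
    cand <- pick_primer(flank_seq, p, rev_primer_len)
    if (!is.null(cand)) { rv <- cand; break }
  }
  if (is.null(rv)) stopf("no acceptable common reverse primer in product range")
  structure(list(
    allele1_forward = paste0(KASP_TAIL_FAM, fwd1),
    allele2_forward = paste0(KASP_TAIL_HEX, fwd2),
    common_reverse = revcomp(rv$seq),
    tail1 = KASP_TAIL_FAM, tail2 = KASP_TAIL_HEX,
    allele1_untailed = fwd1, allele2_untailed = fwd2,
    variant = list(pos = variant_pos, ref = toupper(ref_base),
                   alt = toupper(alt_base)),
    product_length = rv$start + rev_primer_len - 1 - p_start + 1),
    class = "kasp_primer_set")
}

#' Check the structural invariants of a KASP primer set
#'
#' The two untailed forward primers must be identical except their
#' 3'-terminal base, and the tails must be prepended to the forwards only.
#'
#' @param set a `kasp_primer_set`.
#' @return TRUE invisibly; errors otherwise.
#' @export
validate_kasp <- function(set) {
  f1 <- set$allele1_untailed; f2 <- set$allele2_untailed
  if (nchar(f1) != nchar(f2)) stopf("forward primers differ in length")
  diffs <- which(strsplit(f1, "")[[1]] != strsplit(f2, "")[[1]])
  if (!identical(diffs, nchar(f1)))
    stopf("forward primers must differ only at the 3'-terminal base")
  if (!startsWith(set$allele1_forward, set$tail1) ||
      !startsWith(set$allele2_forward, set$tail2))
    stopf("tails must be prepended to the forward primers")
  if (substr(set$allele1_forward, nchar(set$tail1) + 1, nchar(set$allele1_forward)) != f1)
    stopf("tailed forward 1 does not contain the untailed primer")
  invisible(TRUE)
}
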