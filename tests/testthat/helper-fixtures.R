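# shared fixture builders; everything is generated in code at test time

# minimal callset from vectors, defaulting to hom_alt SNPs
make_cs <- function(sample, chrom, pos, ref = "A", alt = "G",
                    genotype = "hom_alt", reference = "ref", ...) {
  n <- max(lengths(list(chrom, pos, ref, alt, genotype)))
  rec <- data.frame(chrom = rep_len(chrom, n), pos = rep_len(pos, n),
                    ref = rep_len(ref, n), alt = rep_len(alt, n),
                    genotype = rep_len(genotype, n), ...)
  callset(sample, reference, rec)
}

# deterministic CDS: Ala codons with AGC at codon 627 and GTG at codon 643,
# so position 1880 sits mid-codon 627 and 1927 starts codon 643
make_als_like_cds <- function(n_codons = 650) {
  codons <- rep("GCT", n_codons)
  codons[627] <- "AGC"
  codons[643] <- "GTG"
  paste(codons, collapse = "")
}

# brute-force single-site origin oracle, written independently of
# classify_trio: explicit rule-by-rule evaluation of one site
origin_oracle <- function(gt_improved, gt_receptor_same_alt, gt_donor_same_alt) {
  if (gt_improved %in% c("hom_ref", "missing")) return(NA_character_)
  if (gt_improved == "het") return("heterozygous")
  if (!is.na(gt_receptor_same_alt) && gt_receptor_same_alt == "hom_alt")
    return("receptor")
  if (!is.na(gt_donor_same_alt) && gt_donor_same_alt == "hom_alt")
    return("donor")
  "unknown"
}

# bp-level overlap of two interval sets on one chromosome set
interval_overlap_bp <- function(a, b) {
  if (!nrow(a) || !nrow(b)) return(0)
  ga <- GenomicRanges::GRanges(a$chrom, IRanges::IRanges(a$start, a$end))
  gb <- GenomicRanges::GRanges(b$chrom, IRanges::IRanges(b$start, b$end))
  sum(IRanges::width(GenomicRanges::intersect(ga, gb)))
}
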