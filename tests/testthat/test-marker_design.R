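test_that("CDS annotation agrees with an independent codon-table lookup", {
  skip_if_not_installed("seqinr")
  # all 9 single-base substitutions of a handful of codons, in all 3 frames
  cds <- paste0("ATG", "AGC", "GTG", "CTG", "TGG", "TAT", "GCT", "TCA", "TAA")
  pad <- strrep("GCT", 4)
  cds <- paste0(cds, pad)  # length divisible by 3
  bases <- c("A", "C", "G", "T")
  for (pos in seq_len(nchar(cds) - 3)) {   # skip the terminal stop codon
    refb <- substr(cds, pos, pos)
    for (altb in setdiff(bases, refb)) {
      ann <- annotate_cds_variant(cds, pos, refb, altb)
      mut <- cds
      substr(mut, pos, pos) <- altb
      aa_ref <- seqinr::translate(strsplit(cds, "")[[1]])
      aa_alt <- seqinr::translate(strsplit(mut, "")[[1]])
      cn <- ceiling(pos / 3)
      expect_identical(ann$ref_aa, aa_ref[cn])
      expect_identical(ann$alt_aa, aa_alt[cn])
      want_eff <- if (aa_ref[cn] == aa_alt[cn]) "synonymous"
                  else if (aa_alt[cn] == "*") "nonsense" else "missense"
      expect_identical(ann$effect, want_eff)
      expect_equal(ann$codon_number, cn)
    }
  }
})

test_that("herbicide-tolerance substitutions annotate to S627N and V643M", {
  cds <- make_als_like_cds()
  a <- annotate_cds_variant(cds, 1880, "G", "A")
  expect_identical(a$label, "S627N")
  expect_identical(a$effect, "missense")
  b <- annotate_cds_variant(cds, 1927, "G", "A")
  expect_identical(b$label, "V643M")
  # third-position wobble is synonymous (CTG -> CTA, both Leu)
  w <- annotate_cds_variant("CTG", 3, "G", "A")
  expect_identical(w$effect, "synonymous")
  expect_error(annotate_cds_variant(cds, 1880, "C", "A"), "observed G")
  expect_error(annotate_cds_variant("ACGT", 1, "A", "G"), "divisible by 3")
})

test_that("linked-InDel search uses a closed interval and sorts by distance", {
  rec <- data.frame(
    chrom = "chr2",
    pos = c(100, 500, 1000, 1500, 2000),
    ref = c("G", paste0("A", strrep("T", 49)), paste0("A", strrep("T", 10)),
            paste0("A", strrep("T", 30)), paste0("A", strrep("T", 25))),
    alt = "A", genotype = "hom_alt")
  cs <- callset("donor", "ref", rec)
  # target at 1000, flank 500: InDels at 500, 1000, 1500 are in the closed window;
  # the 10 bp one at 1000 is below min_len, the SNP at 100 is not an InDel
  out <- find_linked_indels(cs, "chr2", 1000, flank_bp = 500,
                            min_len = 20, max_len = 80)
  expect_equal(out$pos, c(500, 1500))
  expect_equal(out$distance, c(500, 500))
  expect_equal(nrow(find_linked_indels(cs, "chr2", 1e5, 100)), 0L)
  # planted InDels from the amplicon simulator are all rediscovered
  sim <- simulate_amplicons(n_indel = 3, indel_sizes = c(49, 24, 41),
                            n_caps = 0, seed = 6)
  rec2 <- data.frame(chrom = "chr2", pos = 1000 + seq_len(3) * 100,
                     ref = vapply(sim$truth$indel_len,
                                  function(l) paste0("A", strrep("T", l)), ""),
                     alt = "A", genotype = "hom_alt")
  out2 <- find_linked_indels(callset("d", "ref", rec2), "chr2", 1000, 1000)
  expect_equal(sort(abs(nchar(out2$ref) - nchar(out2$alt))), c(24, 41, 49))
})

test_that("in-silico PCR matches a brute-force string-search oracle", {
  set.seed(12)
  for (i in 1:20) {
    n <- 300
    tpl <- paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
    f_start <- sample(1:80, 1)
    r_end <- sample(200:n, 1)
    fwd <- substr(tpl, f_start, f_start + 19)
    rev_site <- substr(tpl, r_end - 19, r_end)
    rev <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(rev_site)))
    res <- insilico_pcr(tpl, fwd, rev)
    # oracle: exact substring scan
    f_hits <- gregexpr(fwd, tpl, fixed = TRUE)[[1]]
    r_hits <- gregexpr(rev_site, tpl, fixed = TRUE)[[1]]
    if (length(f_hits) == 1 && f_hits[1] > 0 && length(r_hits) == 1) {
      expect_identical(res$status, "ok")
      expect_equal(res$length, r_hits[1] + 20 - f_hits[1])
    } else {
      expect_identical(res$status, "multiple_sites")
    }
  }
  expect_identical(insilico_pcr(strrep("A", 100), strrep("C", 20),
                                strrep("G", 20))$status, "no_fwd_site")
  expect_error(insilico_pcr("ACGT", "ACGT", "ACGT"), ">= 15")
})

test_that("allele product sizes of an InDel marker differ by the InDel length", {
  sim <- simulate_amplicons(n_indel = 3, indel_sizes = c(49, 24, 41),
                            n_caps = 0, amplicon_length = 250, seed = 14)
  for (i in 1:3) {
    t_i <- sim$truth[i, ]
    m <- design_indel_marker(sim$ref_seqs[[t_i$id]], t_i$pos, t_i$indel_len)
    expect_false(is.null(m))
    expect_equal(m$size_difference, t_i$indel_len)
    expect_equal(m$product_length_ref - m$product_length_alt, t_i$indel_len)
  }
  # out-of-range indels are rejected
  expect_null(design_indel_marker(strrep("ACGT", 100), 100, 5))
})

test_that("digest fragments partition the amplicon with correct cut offsets", {
  # no site: one full-length fragment
  expect_equal(insilico_digest(strrep("A", 57), "HinfI"), 57L)
  # one GANTC starting at position 101 of a 220 bp amplicon cuts G^ANTC
  amp <- paste0(strrep("A", 100), "GACTC", strrep("T", 115))
  expect_equal(insilico_digest(amp, "HinfI"), c(101L, 119L))
  # motif-with-caret spelling and list spelling agree with the built-in
  expect_equal(insilico_digest(amp, "G^ANTC"), c(101L, 119L))
  expect_equal(insilico_digest(amp, list(motif = "GANTC", cut_offset = 1)),
               c(101L, 119L))
  expect_error(insilico_digest(amp, "NoSuchEnzyme"), "built-ins")
})

test_that("digest equals a brute-force motif-scan oracle on random sequences", {
  set.seed(77)
  iupac_ok <- function(b, m) {
    opts <- strsplit(Biostrings::IUPAC_CODE_MAP[[m]], "")[[1]]
    b %in% opts
  }
  for (i in 1:50) {
    s <- paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE,
                      prob = c(.3, .2, .3, .2)), collapse = "")
    frags <- insilico_digest(s, "HinfI")
    expect_equal(sum(frags), 400L)
    # oracle: scan every position, emulate leftmost-first digestion
    ch <- strsplit(s, "")[[1]]
    motif <- c("G", "A", "N", "T", "C")
    starts <- which(vapply(1:(400 - 4), function(p)
      all(mapply(iupac_ok, ch[p:(p + 4)], motif)), logical(1)))
    cuts <- integer(0); last <- -1L
    for (p in starts) {
      if (last >= p && last <= p + 3L) next
      cuts <- c(cuts, p); last <- p
    }
    expect_equal(frags, as.integer(diff(c(0L, cuts, 400L))))
  }
})

test_that("CAPS design requires the site in exactly one allele", {
  pad1 <- "TTTTTTTTTT"; pad2 <- "AAAAAAAAAA"
  # both alleles carry a HinfI site (GAGTC / GACTC both match GANTC): no marker
  both <- design_caps(paste0(pad1, "GAGTC", pad2), paste0(pad1, "GACTC", pad2),
                      enzymes = restriction_enzymes()[1, ])
  expect_null(both)
  # site lost in the alternate allele (GATTC -> GCTTC): marker with 2 vs 1 fragments
  lost <- design_caps(paste0(pad1, "GATTC", pad2), paste0(pad1, "GCTTC", pad2),
                      enzymes = restriction_enzymes()[1, ])
  expect_identical(lost$enzyme, "HinfI")
  expect_identical(lost$site_change, "loss")
  expect_length(lost$fragments_ref, 2L)
  expect_length(lost$fragments_alt, 1L)
  expect_equal(sum(lost$fragments_ref), sum(lost$fragments_alt))
  # simulated site-altering SNPs are all detected
  sim <- simulate_amplicons(n_indel = 0, n_caps = 4, seed = 18)
  for (id in sim$truth$id) {
    cp <- design_caps(sim$ref_seqs[[id]], sim$donor_seqs[[id]])
    expect_identical(cp$marker_type, "caps")
    expect_identical(cp$site_change, "loss")
  }
  expect_error(design_caps("AAAA", "AAAA"), "exactly one")
})

test_that("KASP primer sets differ only at the 3'-terminal base, tails prepended", {
  # validation fixture shaped like the published tolerance-allele assay:
  # allele-specific region ATCATGTCCTTGAATGCGCCCCCA + T/C terminal base
  region <- "ATCATGTCCTTGAATGCGCCCCCA"
  set.seed(30)
  right <- paste(sample(c("A", "C", "G", "T"), 120, replace = TRUE), collapse = "")
  flank <- paste0("G", region, "T", right)
  vpos <- nchar(region) + 2
  ks <- design_kasp(flank, vpos, "T", "C", allele_primer_len = 25)
  expect_identical(ks$allele1_untailed, paste0(region, "T"))
  expect_identical(ks$allele2_untailed, paste0(region, "C"))
  expect_identical(ks$tail1, "GAAGGTGACCAAGTTCATGCT")
  expect_identical(ks$tail2, "GAAGGTCGGAGTCAACGGATT")
  expect_true(validate_kasp(ks))

  # variant base equal to its complement context still yields one difference
  pal <- paste0(strrep("AT", 20), "GCGC", strrep("TA", 30))
  kp <- design_kasp(pal, 30, substr(pal, 30, 30),
                    chartr("ACGT", "TGCA", substr(pal, 30, 30)))
  expect_true(validate_kasp(kp))

  expect_error(design_kasp("ACGTACGTACGT", 6, "C", "T"), "flank too short")
})

test_that("random-variant KASP designs all satisfy the structural invariants", {
  set.seed(61)
  n_ok <- 0
  for (i in 1:100) {
    flank <- paste(sample(c("A", "C", "G", "T"), 220, replace = TRUE), collapse = "")
    vpos <- sample(30:120, 1)
    refb <- substr(flank, vpos, vpos)
    altb <- sample(setdiff(c("A", "C", "G", "T"), refb), 1)
    ks <- tryCatch(design_kasp(flank, vpos, refb, altb), error = function(e) NULL)
    if (is.null(ks)) next      # no acceptable reverse primer in range
    n_ok <- n_ok + 1
    expect_true(validate_kasp(ks))
    expect_identical(substr(ks$allele2_untailed, nchar(ks$allele2_untailed),
                            nchar(ks$allele2_untailed)), altb)
  }
  expect_gt(n_ok, 90)  # designs should almost always succeed on random flanks
})
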