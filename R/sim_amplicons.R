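#' Simulate allele pairs of marker amplicons with planted polymorphisms
#'
#' Generates pairs of amplicon sequences (reference allele, donor allele) that
#' differ by exactly one planted polymorphism: either a deletion of a given
#' size in the donor allele (an InDel marker locus) or a single SNP that
#' destroys a restriction-enzyme recognition site present in the reference
#' allele (a CAPS marker locus). Background sequence is scrubbed of accidental
#' motif occurrences so the planted site is the only one, and a 30 bp
#' primer-able flank is kept free of the polymorphism on both ends.
#'
#' @param n_indel number of InDel pairs; `indel_sizes` is recycled to this
#'   length.
#' @param indel_sizes deletion sizes (bp, >= 1) planted in the donor alleles.
#' @param n_caps number of CAPS pairs (enzyme site lost in the donor allele).
#' @param enzyme_site IUPAC recognition motif planted for CAPS pairs.
#' @param amplicon_length length of every reference-allele amplicon.
#' @param seed integer seed.
#' @return list with `ref_seqs` and `donor_seqs` (named character vectors) and
#'   `truth`: data.frame of pair id, type (`indel`/`caps`), polymorphism
#'   position on the reference allele, indel length (NA for caps) and
#'   `site_change` (`"loss"` for caps pairs, NA otherwise).
#' @export
#' @examples
#' sim <- simulate_amplicons(n_indel = 1, indel_sizes = 49,
#'                           amplicon_length = 191, seed = 1)
#' nchar(sim$donor_seqs[1])  # 142
simulate_amplicons <- function(n_indel = 3, indel_sizes = c(49, 24, 41),
                               n_caps = 1, enzyme_site = "GANTC",
                               amplicon_length = 191, seed = 1) {
  if (any(indel_sizes < 1)) stopf("indel sizes must be >= 1")
  flank <- 30L
  if (n_indel > 0 && amplicon_length < flank * 2 + max(indel_sizes) + 2)
    stopf("amplicon_length too short for the requested indel sizes")
  set.seed(seed)
  sizes <- rep_len(indel_sizes, n_indel)
  ids <- paste0("amp", seq_len(n_indel + n_caps))
  ref_seqs <- donor_seqs <- character(0)
  truth <- list()

  for (i in seq_len(n_indel)) {
    s <- sizes[i]
    ref <- scrub_motif(random_dna(amplicon_length), enzyme_site)
    start <- sample(seq(flank + 1L, amplicon_length - flank - s + 1L), 1)
    donor <- paste0(substr(ref, 1, start - 1L),
                    substr(ref, start + s, amplicon_length))
    ref_seqs <- c(ref_seqs, ref); donor_seqs <- c(donor_seqs, donor)
    truth[[length(truth) + 1L]] <- data.frame(
      id = ids[i], type = "indel", pos = start, indel_len = s,
      site_change = NA_character_, stringsAsFactors = FALSE)
  }

  for (j in seq_len(n_caps)) {
    ref <- scrub_motif(random_dna(amplicon_length), enzyme_site)
    concrete <- instantiate_iupac(enzyme_site)
    k <- nchar(concrete)
    start <- sample(seq(flank + 1L, amplicon_length - flank - k + 1L), 1)
    ref <- paste0(substr(ref, 1, start - 1L), concrete,
                  substr(ref, start + k, amplicon_length))
    ref <- plant_only(ref, enzyme_site, start, k)
    # destroy the site with a single substitution at its first base
    old <- substr(ref, start, start)
    donor <- ref
    for (b in setdiff(DNA_BASES, old)) {
      cand <- paste0(substr(ref, 1, start - 1L), b,
                     substr(ref, start + 1L, amplicon_length))
      if (length(motif_matches(cand, enzyme_site)) == 0L) { donor <- cand; break }
    }
    ref_seqs <- c(ref_seqs, ref); donor_seqs <- c(donor_seqs, donor)
    truth[[length(truth) + 1L]] <- data.frame(
      id = ids[n_indel + j], type = "caps", pos = start, indel_len = NA_real_,
      site_change = "loss", stringsAsFactors = FALSE)
  }

  names(ref_seqs) <- names(donor_seqs) <- ids
  list(ref_seqs = ref_seqs, donor_seqs = donor_seqs,
       truth = do.call(rbind, truth))
}

# all start positions of an IUPAC motif in seq (1-based, overlapping allowed)
motif_matches <- function(seq, motif) {
  m <- Biostrings::matchPattern(Biostrings::DNAString(motif),
                                Biostrings::DNAString(seq), fixed = FALSE)
  BiocGenerics::start(m)
}

# mutate one base inside every motif occurrence until none remain
scrub_motif <- function(seq, motif) {
  repeat {
    hits <- motif_matches(seq, motif)
    if (!length(hits)) return(seq)
    p <- hits[1]
    old <- substr(seq, p, p)
    repl <- sample(setdiff(DNA_BASES, old), 1)
    seq <- paste0(substr(seq, 1, p - 1L), repl,
                  substr(seq, p + 1L, nchar(seq)))
  }
}

# re-scrub accidental motifs created by planting, without touching the
# planted occurrence at [start, start+k-1]
plant_only <- function(seq, motif, start, k) {
  planted <- start:(start + k - 1L)
  repeat {
    hits <- setdiff(motif_matches(seq, motif), start)
    if (!length(hits)) return(seq)
    p <- hits[1]
    fixed <- FALSE
    for (q in setdiff(p:(p + k - 1L), planted)) {
      for (b in setdiff(DNA_BASES, substr(seq, q, q))) {
        cand <- paste0(substr(seq, 1, q - 1L), b,
                       substr(seq, q + 1L, nchar(seq)))
        if (!p %in% motif_matches(cand, motif)) {
          seq <- cand; fixed <- TRUE; break
        }
      }
      if (fixed) break
    }
    if (!fixed) stopf("cannot scrub motif occurrence overlapping planted site")
  }
}

# one concrete instance of an IUPAC motif
instantiate_iupac <- function(motif) {
  map <- Biostrings::IUPAC_CODE_MAP
  paste(vapply(strsplit(motif, "")[[1]], function(ch) {
    opts <- strsplit(map[[toupper(ch)]], "")[[1]]
    sample(opts, 1)
  }, ""), collapse = "")
}

#' Write named sequences to a FASTA file
#'
#' @param seqs named character vector of DNA sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a FASTA file as a named character vector
#'
#' @param path FASTA path.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}
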