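#' Configuration for the trio genome simulator
#'
#' Describes the breeding scenario the simulator emulates: a donor variety and
#' an elite receptor parent, both called against a common reference, and an
#' improved line that is the receptor background carrying donor-derived
#' segments (including one around the target locus). A minority of the
#' improved line's SNPs come from a third, unknown origin and are placed in
#' sub-clusters; a small fraction of sites is heterozygous.
#'
#' Defaults scale the published scenario onto a 12 x 2 Mb genome: SNP density
#' of 1e-3/bp per parent (several hundred thousand SNPs on a real ~370 Mb rice
#' genome scale to tens of thousands here), a ~0.4 Mb donor block around the
#' target-locus position on chr2 (5-10 Mb on a real ~36 Mb chromosome) plus
#' six further donor blocks on other chromosomes (donor share ~12% of
#' improved-line sites, at the low end of the published 12.75-20.21% range), an
#' unknown-origin fraction of 7% in three
#' sub-clusters and a heterozygous fraction of 0.4%.
#'
#' @param genome a [genome_index()].
#' @param donor_density,receptor_density expected SNPs per bp for
#'   donor-vs-reference and receptor-vs-reference.
#' @param introgression_segments list of `c(chrom, start, end)` donor blocks
#'   (1-based inclusive) present in the improved line.
#' @param unknown_fraction proportion of improved-line SNP sites carrying a
#'   third allele absent from both parents.
#' @param het_fraction proportion of improved-line sites emitted heterozygous.
#' @param n_unknown_clusters number of sub-clusters the unknown sites are
#'   placed in (clustered, as observed for third-origin SNPs, rather than
#'   uniform).
#' @param seed integer; fixes all randomness.
#' @return a `trio_sim_config` list.
#' @export
trio_sim_config <- function(genome = default_genome(),
                            donor_density = 1e-3,
                            receptor_density = 1e-3,
                            introgression_segments = list(
                              c("chr2", 8e5, 12e5),
                              c("chr1", 14e5, 19e5),
                              c("chr3", 2e5, 7e5),
                              c("chr5", 1e5, 5e5),
                              c("chr6", 9e5, 13e5),
                              c("chr7", 10e5, 14e5),
                              c("chr12", 1e5, 5e5)),
                            unknown_fraction = 0.07,
                            het_fraction = 0.004,
                            n_unknown_clusters = 3,
                            seed = 1) {
  stopifnot(inherits(genome, "genome_index"))
  if (unknown_fraction < 0 || het_fraction < 0 ||
      unknown_fraction + het_fraction >= 1)
    stopf("unknown_fraction and het_fraction must be in [0,1) and sum to < 1")
  segs <- do.call(rbind, lapply(introgression_segments, function(s) {
    data.frame(chrom = as.character(s[1]), start = as.numeric(s[2]),
               end = as.numeric(s[3]), stringsAsFactors = FALSE)
  }))
  if (!is.null(segs)) {
    m <- match(segs$chrom, genome$chrom)
    if (anyNA(m)) stopf("segment chromosome not in genome")
    if (any(segs$start < 1) || any(segs$end > genome$length[m]) ||
        any(segs$end <= segs$start))
      stopf("segments must lie within chromosome bounds with end > start")
    for (ch in unique(segs$chrom)) {
      s <- segs[segs$chrom == ch, ]
      s <- s[order(s$start), ]
      if (nrow(s) > 1 && any(s$start[-1] <= s$end[-nrow(s)]))
        stopf("overlapping introgression segments on %s", ch)
    }
  }
  structure(list(genome = genome, donor_density = donor_density,
                 receptor_density = receptor_density, segments = segs,
                 unknown_fraction = unknown_fraction,
                 het_fraction = het_fraction,
                 n_unknown_clusters = n_unknown_clusters,
                 seed = as.integer(seed)),
            class = "trio_sim_config")
}

# Poisson SNP placement along one chromosome; hom_alt biallelic records
sample_parent_snps <- function(genome, density) {
  recs <- lapply(seq_len(nrow(genome)), function(i) {
    len <- genome$length[i]
    n <- stats::rpois(1, len * density)
    n <- min(n, len)
    pos <- sort(sample.int(len, n))
    ref <- sample(DNA_BASES, n, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(DNA_BASES, r), 1), "")
    data.table::data.table(chrom = genome$chrom[i], pos = as.numeric(pos),
                           ref = ref, alt = unname(alt), genotype = "hom_alt")
  })
  data.table::rbindlist(recs)
}

in_segments <- function(chrom, pos, segs) {
  if (is.null(segs) || !nrow(segs)) return(rep(FALSE, length(pos)))
  hit <- rep(FALSE, length(pos))
  for (i in seq_len(nrow(segs))) {
    hit <- hit | (chrom == segs$chrom[i] & pos >= segs$start[i] & pos <= segs$end[i])
  }
  hit
}

#' Simulate a donor / receptor / improved-line trio with known truth
#'
#' Draws donor-vs-reference and receptor-vs-reference SNPs as independent
#' Poisson processes per chromosome, then composes the improved line by
#' segment copy: donor genotypes inside the configured introgression segments,
#' receptor genotypes outside. Unknown-origin SNPs (third allele, absent from
#' both parents) are added in sub-clusters, and a fraction of improved sites
#' is flipped heterozygous. Ground-truth origin labels are exact by
#' construction and use the same receptor-before-donor precedence as
#' [classify_trio()] at sites where both parents share the allele.
#'
#' @param cfg a [trio_sim_config()].
#' @return list with `donor`, `receptor`, `improved` ([callset()]s), and
#'   `truth`: a list of `origins` (chrom, pos, category) and `segments`.
#' @export
simulate_trio <- function(cfg) {
  stopifnot(inherits(cfg, "trio_sim_config"))
  genome <- cfg$genome
  segs <- cfg$segments

  set.seed(derive_seed(cfg$seed, 1L))
  donor_rec <- sample_parent_snps(genome, cfg$donor_density)
  set.seed(derive_seed(cfg$seed, 2L))
  receptor_rec <- sample_parent_snps(genome, cfg$receptor_density)

  set.seed(derive_seed(cfg$seed, 3L))
  d_in <- in_segments(donor_rec$chrom, donor_rec$pos, segs)
  r_in <- in_segments(receptor_rec$chrom, receptor_rec$pos, segs)
  improved <- rbind(donor_rec[d_in], receptor_rec[!r_in])
  origin <- c(rep("donor_segment", sum(d_in)), rep("receptor", sum(!r_in)))

  # receptor-before-donor precedence for shared-allele sites inside segments
  shared <- improved[origin == "donor_segment"][
    receptor_rec, on = c("chrom", "pos", "alt"), nomatch = NULL]
  truth_cat <- ifelse(origin == "donor_segment", "donor", "receptor")
  if (nrow(shared)) {
    key <- paste(improved$chrom, improved$pos, improved$alt)
    truth_cat[key %in% paste(shared$chrom, shared$pos, shared$alt)] <- "receptor"
  }

  # clustered unknown-origin sites with a third allele
  n_base <- nrow(improved)
  n_unknown <- round(cfg$unknown_fraction / (1 - cfg$unknown_fraction) * n_base)
  if (n_unknown > 0) {
    occupied <- unique(rbind(donor_rec[, .(chrom, pos)], receptor_rec[, .(chrom, pos)]))
    centers <- data.frame(
      chrom = sample(genome$chrom, cfg$n_unknown_clusters, replace = TRUE))
    centers$len <- genome$length[match(centers$chrom, genome$chrom)]
    centers$mid <- floor(stats::runif(cfg$n_unknown_clusters, 0.1, 0.9) * centers$len)
    per <- diff(round(seq(0, n_unknown, length.out = cfg$n_unknown_clusters + 1)))
    urec <- data.table::rbindlist(lapply(seq_len(cfg$n_unknown_clusters), function(i) {
      w <- max(1e4, 0.05 * centers$len[i])   # cluster half-width ~5% of chromosome
      p <- unique(floor(stats::runif(per[i] * 2, centers$mid[i] - w, centers$mid[i] + w)))
      p <- p[p >= 1 & p <= centers$len[i]]
      data.table::data.table(chrom = centers$chrom[i], pos = as.numeric(p))
    }))
    urec <- urec[!occupied, on = c("chrom", "pos")]
    urec <- unique(urec, by = c("chrom", "pos"))
    urec <- urec[seq_len(min(nrow(urec), n_unknown))]
    if (nrow(urec)) {
      urec[, ref := sample(DNA_BASES, .N, replace = TRUE)]
      urec[, alt := vapply(ref, function(r) sample(setdiff(DNA_BASES, r), 1), "")]
      urec[, genotype := "hom_alt"]
      improved <- rbind(improved, urec)
      truth_cat <- c(truth_cat, rep("unknown", nrow(urec)))
    }
  }

  # heterozygous fraction across all improved sites
  if (cfg$het_fraction > 0 && nrow(improved)) {
    n_het <- round(cfg$het_fraction * nrow(improved))
    idx <- sample.int(nrow(improved), min(n_het, nrow(improved)))
    improved[idx, genotype := "het"]
    truth_cat[idx] <- "heterozygous"
  }

  ord <- order(improved$chrom, improved$pos)
  improved <- improved[ord]
  truth_cat <- truth_cat[ord]

  list(
    donor = callset("donor", "synthetic_ref", donor_rec),
    receptor = callset("receptor", "synthetic_ref", receptor_rec),
    improved = callset("improved", "synthetic_ref", improved),
    truth = list(
      origins = data.table::data.table(chrom = improved$chrom,
                                       pos = improved$pos,
                                       category = truth_cat),
      segments = segs
    )
  )
}

#' Deterministic trio fixture with exact per-category site counts
#'
#' Builds donor/receptor/improved call sets whose [classify_trio()] partition
#' has exactly the requested number of donor-specific, receptor-parent,
#' heterozygous and unknown sites. Used to reconstruct published SNP partition
#' tables at full size without randomness: sites are laid out consecutively
#' round-robin across the genome's chromosomes.
#'
#' @param n_donor,n_receptor,n_het,n_unknown per-category site counts.
#' @param genome optional [genome_index()]; defaults to 12 chromosomes just
#'   long enough to hold the sites.
#' @return list with `donor`, `receptor`, `improved` call sets.
#' @export
#' @examples
#' tr <- trio_from_counts(5, 10, 1, 2)
#' classify_trio(tr$improved, tr$donor, tr$receptor)$summary
trio_from_counts <- function(n_donor, n_receptor, n_het, n_unknown,
                             genome = NULL) {
  total <- n_donor + n_receptor + n_het + n_unknown
  if (is.null(genome)) {
    per_chrom <- ceiling(total / 12) + 1
    genome <- genome_index(paste0("chr", 1:12), rep(per_chrom * 10, 12))
  }
  cat_vec <- rep(c("donor", "receptor", "heterozygous", "unknown"),
                 times = c(n_donor, n_receptor, n_het, n_unknown))
  chrom_idx <- rep(seq_len(nrow(genome)), length.out = total)
  # consecutive 10 bp slots per chromosome
  pos <- stats::ave(seq_len(total), chrom_idx, FUN = seq_along) * 10
  chrom <- genome$chrom[chrom_idx]

  improved <- data.table::data.table(
    chrom = chrom, pos = as.numeric(pos), ref = "A",
    alt = ifelse(cat_vec == "unknown", "T", "G"),
    genotype = ifelse(cat_vec == "heterozygous", "het", "hom_alt"))
  donor <- improved[cat_vec == "donor",
                    .(chrom, pos, ref, alt, genotype = "hom_alt")]
  receptor <- improved[cat_vec == "receptor",
                       .(chrom, pos, ref, alt, genotype = "hom_alt")]
  list(
    donor = callset("donor", "synthetic_ref", donor),
    receptor = callset("receptor", "synthetic_ref", receptor),
    improved = callset("improved", "synthetic_ref", improved)
  )
}
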