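make_sites <- function(chrom, pos, category) {
  data.frame(chrom = chrom, pos = pos, category = category,
             stringsAsFactors = FALSE)
}

test_that("window tiling counts sites in every overlapping window", {
  g <- genome_index("chr1", 1000)
  empty <- make_sites(character(), numeric(), character())
  tr0 <- windowed_density(empty, g, window = 100, step = 50)
  expect_true(all(tr0$n_total == 0))
  expect_equal(min(tr0$start), 1)
  expect_equal(max(tr0$end), 1000)

  # one interior SNP is counted in ceiling(window/step) windows
  tr1 <- windowed_density(make_sites("chr1", 500, "donor"), g,
                          window = 100, step = 50)
  expect_equal(sum(tr1$n_total), ceiling(100 / 50))
  expect_equal(sum(tr1$n_donor), 2)
  # an edge SNP is counted in fewer windows
  tr2 <- windowed_density(make_sites("chr1", 10, "donor"), g,
                          window = 100, step = 50)
  expect_equal(sum(tr2$n_total), 1)
})

test_that("a window longer than the chromosome warns and truncates", {
  g <- genome_index("chr1", 300)
  expect_warning(tr <- windowed_density(make_sites("chr1", 10, "donor"), g,
                                        window = 1000, step = 1000),
                 "truncated")
  expect_equal(tr$end[1], 300)
})

test_that("uniform-density window counts stay within Poisson bounds", {
  set.seed(99)
  g <- genome_index("chr1", 1e6)
  lambda_bp <- 5e-4
  n <- rpois(1, 1e6 * lambda_bp)
  sites <- make_sites("chr1", sort(sample.int(1e6, n)), "receptor")
  tr <- windowed_density(sites, g, window = 1e5, step = 1e5)
  mu <- lambda_bp * 1e5
  expect_true(all(abs(tr$n_total - mu) < 4 * sqrt(mu)))
})

test_that("no donor sites means no donor blocks", {
  g <- genome_index("chr1", 1e5)
  sites <- make_sites("chr1", seq(1000, 9e4, 1000), "receptor")
  tr <- windowed_density(sites, g, window = 1e4, step = 5e3)
  expect_equal(nrow(call_blocks(tr, category = "donor")), 0L)
})

test_that("a planted donor segment is recovered as one block with >= 90% reciprocal overlap", {
  cfg <- trio_sim_config(genome = default_genome(2e6, 2), seed = 31,
                         introgression_segments = list(c("chr2", 5e5, 10e5)),
                         unknown_fraction = 0, het_fraction = 0)
  tr <- simulate_trio(cfg)
  tab <- classify_trio(tr$improved, tr$donor, tr$receptor)
  track <- windowed_density(tab, cfg$genome, window = 1e5, step = 5e4)
  bl <- call_blocks(track, category = "donor", table = tab)
  expect_equal(nrow(bl), 1L)
  truth <- data.frame(chrom = "chr2", start = 5e5, end = 10e5)
  ov <- interval_overlap_bp(bl, truth)
  expect_gte(ov / (truth$end - truth$start + 1), 0.9)
  expect_gte(ov / (sum(bl$end - bl$start + 1)), 0.9)
})

test_that("clustered unknown-origin sites are called as unknown blocks, not donor", {
  cfg <- trio_sim_config(genome = default_genome(1e6, 4), seed = 23,
                         introgression_segments = list(c("chr2", 3e5, 6e5)),
                         unknown_fraction = 0.08, n_unknown_clusters = 2)
  tr <- simulate_trio(cfg)
  tab <- classify_trio(tr$improved, tr$donor, tr$receptor)
  track <- windowed_density(tab, cfg$genome, window = 5e4, step = 25e3)
  bl_d <- call_blocks(track, category = "donor", table = tab)
  bl_u <- call_blocks(track, category = "unknown", table = tab)
  expect_gte(nrow(bl_u), 1L)
  # unknown blocks do not sit inside the donor segment
  expect_equal(interval_overlap_bp(bl_u,
               data.frame(chrom = "chr2", start = 3e5, end = 6e5)), 0)
  # and the donor calls all lie on chr2
  expect_true(all(bl_d$chrom == "chr2"))
})

test_that("raising min_fraction never adds blocks nor widens any block", {
  for (seed in c(41, 42, 43)) {
    cfg <- trio_sim_config(genome = default_genome(1e6, 3), seed = seed,
                           introgression_segments = list(c("chr2", 2e5, 5e5),
                                                         c("chr3", 1e5, 3e5)))
    tr <- simulate_trio(cfg)
    tab <- classify_trio(tr$improved, tr$donor, tr$receptor)
    track <- windowed_density(tab, cfg$genome, window = 5e4, step = 25e3)
    lo <- call_blocks(track, min_fraction = 0.3, category = "donor")
    hi <- call_blocks(track, min_fraction = 0.7, category = "donor")
    expect_lte(nrow(hi), nrow(lo))
    # every stricter block is contained in a looser one
    for (i in seq_len(nrow(hi))) {
      inside <- lo$chrom == hi$chrom[i] & lo$start <= hi$start[i] &
        lo$end >= hi$end[i]
      expect_true(any(inside))
    }
  }
})

test_that("reported blocks contain at least min_snps sites of their category", {
  cfg <- trio_sim_config(genome = default_genome(1e6, 3), seed = 51,
                         introgression_segments = list(c("chr2", 2e5, 5e5)))
  tr <- simulate_trio(cfg)
  tab <- classify_trio(tr$improved, tr$donor, tr$receptor)
  track <- windowed_density(tab, cfg$genome, window = 5e4, step = 25e3)
  bl <- call_blocks(track, min_snps = 10, category = "donor", table = tab)
  sites <- tab$sites[tab$sites$category == "donor", ]
  for (i in seq_len(nrow(bl))) {
    n <- sum(sites$chrom == bl$chrom[i] & sites$pos >= bl$start[i] &
               sites$pos <= bl$end[i])
    expect_gte(n, 10)
    expect_equal(n, bl$n_snps[i])
  }
})

test_that("exported tracks use 0-based half-open coordinates and round-trip", {
  g <- genome_index("chr2", 1000)
  sites <- make_sites("chr2", c(5, 50, 95), "donor")
  track <- windowed_density(sites, g, window = 100, step = 100)
  blocks <- data.frame(chrom = "chr2", start = 1, end = 100, n_snps = 3,
                       mean_fraction = 1, category = "donor")
  bg <- withr::local_tempfile(fileext = ".bedgraph")
  bed <- withr::local_tempfile(fileext = ".bed")
  export_tracks(track, blocks, bedgraph_path = bg, bed_path = bed)
  bed_fields <- strsplit(readLines(bed)[1], "\t")[[1]]
  expect_identical(bed_fields[1:3], c("chr2", "0", "100"))
  back <- rtracklayer::import(bg)
  tr_nonempty <- track[!is.na(track$donor_fraction), ]
  expect_equal(back$score, tr_nonempty$donor_fraction)
  expect_equal(GenomicRanges::start(back), tr_nonempty$start)

  # no blocks: BED is a header comment only
  export_tracks(track, blocks[0, ], bed_path = bed)
  expect_match(readLines(bed)[1], "^#")
})
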