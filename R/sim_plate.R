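#' Configuration for the KASP plate simulator
#'
#' Emulates an endpoint fluorescence read of a KASP assay: each well yields
#' FAM, HEX and ROX intensities, and genotype clusters appear as groups in the
#' ROX-normalised (FAM/ROX, HEX/ROX) plane — homozygotes for the FAM-coupled
#' allele along the x axis, homozygotes for the HEX-coupled allele along the y
#' axis, heterozygotes in between, and no-template controls (NTC) near the
#' origin.
#'
#' @param genotypes character vector, one entry per well, each one of
#'   `"allele1_hom"`, `"allele2_hom"`, `"het"`, `"ntc"`.
#' @param cluster_means named list of `c(x, y)` normalised cluster centres for
#'   the three genotype classes; must be pairwise distinct.
#' @param dispersion standard deviation of the normalised coordinates around
#'   their cluster centre (same for x and y); > 0.
#' @param ntc_mean,ntc_dispersion centre/sd of the (small) normalised NTC
#'   coordinates.
#' @param rox_mean mean raw ROX intensity (arbitrary units); per-well ROX is
#'   drawn with 5% coefficient of variation.
#' @param marker_id marker name stamped on the plate.
#' @param sample_ids optional per-well sample names; defaults to `S1..Sn`.
#' @param seed integer seed.
#' @return a `plate_sim_config` list.
#' @export
plate_sim_config <- function(genotypes,
                             cluster_means = list(allele1_hom = c(1.0, 0.15),
                                                  allele2_hom = c(0.15, 1.0),
                                                  het = c(0.65, 0.65)),
                             dispersion = 0.03,
                             ntc_mean = 0.04, ntc_dispersion = 0.015,
                             rox_mean = 1000,
                             marker_id = "marker1",
                             sample_ids = NULL,
                             seed = 1) {
  genotypes <- as.character(genotypes)
  if (!length(genotypes)) stopf("plate must have at least one well")
  bad <- setdiff(unique(genotypes), c("allele1_hom", "allele2_hom", "het", "ntc"))
  if (length(bad)) stopf("unknown well genotype(s): %s", paste(bad, collapse = ", "))
  if (dispersion <= 0 || ntc_dispersion <= 0) stopf("dispersions must be > 0")
  m <- do.call(rbind, cluster_means)
  if (anyDuplicated(m)) stopf("cluster means must be pairwise distinct")
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_along(genotypes))
  stopifnot(length(sample_ids) == length(genotypes))
  structure(list(genotypes = genotypes, cluster_means = cluster_means,
                 dispersion = dispersion, ntc_mean = ntc_mean,
                 ntc_dispersion = ntc_dispersion, rox_mean = rox_mean,
                 marker_id = marker_id, sample_ids = sample_ids,
                 seed = as.integer(seed)),
            class = "plate_sim_config")
}

#' Simulate a KASP fluorescence plate with known genotypes
#'
#' Draws normalised (FAM/ROX, HEX/ROX) coordinates around each well's cluster
#' centre, multiplies back by a per-well ROX intensity, and returns raw
#' intensities plus the ground-truth genotype of every well. NTC wells get a
#' low normalised magnitude so a signal threshold between the NTC and
#' genotype-cluster magnitudes flags exactly them.
#'
#' @param cfg a [plate_sim_config()].
#' @return list with `plate` (a [fluorescence_plate()]) and `truth`
#'   (data.frame of well, sample_id, genotype).
#' @export
simulate_plate <- function(cfg) {
  stopifnot(inherits(cfg, "plate_sim_config"))
  set.seed(cfg$seed)
  n <- length(cfg$genotypes)
  xy <- t(vapply(cfg$genotypes, function(g) {
    if (g == "ntc") {
      abs(stats::rnorm(2, cfg$ntc_mean, cfg$ntc_dispersion))
    } else {
      mu <- cfg$cluster_means[[g]]
      pmax(0, stats::rnorm(2, mu, cfg$dispersion))
    }
  }, numeric(2)))
  rox <- stats::rnorm(n, cfg$rox_mean, 0.05 * cfg$rox_mean)
  rox <- pmax(rox, 1)
  wells <- data.table::data.table(
    well = well_ids(n),
    sample_id = cfg$sample_ids,
    fam = xy[, 1] * rox, hex = xy[, 2] * rox, rox = rox)
  list(
    plate = fluorescence_plate(wells, marker_id = cfg$marker_id),
    truth = data.frame(well = wells$well, sample_id = wells$sample_id,
                       genotype = cfg$genotypes, stringsAsFactors = FALSE)
  )
}

# A1..H12, then extra plates appended for n > 96
well_ids <- function(n) {
  ids <- as.vector(t(outer(LETTERS[1:8], 1:12, paste0)))
  if (n <= 96) return(ids[seq_len(n)])
  paste0("P", rep(seq_len(ceiling(n / 96)), each = 96)[seq_len(n)], "_",
         rep(ids, length.out = n))
}
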