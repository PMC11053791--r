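#' Windowed origin-category density along the genome
#'
#' Tiles every chromosome with sliding windows of `window` bp advanced by
#' `step` bp (1-based inclusive internally; the last window is truncated at
#' the chromosome end) and counts classified SNP sites per category in each
#' window. The donor fraction per window is the basis for introgression-block
#' calling and chromosome-painting tracks.
#'
#' @param table a `trio_origin_table` from [classify_trio()].
#' @param genome a [genome_index()].
#' @param window window size in bp.
#' @param step step size in bp; `window >= step > 0`.
#' @return a `window_track` data.frame: chrom, start, end, n_total, n_donor,
#'   n_receptor, n_het, n_unknown, donor_fraction (NA where n_total = 0).
#' @export
windowed_density <- function(table, genome, window = 5e5, step = 2.5e5) {
  stopifnot(inherits(genome, "genome_index"))
  if (!(window >= step && step > 0)) stopf("need window >= step > 0")
  if (any(window > genome$length))
    warnf("window exceeds length of %d chromosome(s); single truncated window used",
          sum(window > genome$length))
  sites <- if (inherits(table, "trio_origin_table")) table$sites else
    data.table::as.data.table(table)

  win <- data.table::rbindlist(lapply(seq_len(nrow(genome)), function(i) {
    starts <- seq(1, genome$length[i], by = step)
    data.table::data.table(chrom = genome$chrom[i], start = starts,
                           end = pmin(starts + window - 1, genome$length[i]))
  }))

  wgr <- GenomicRanges::GRanges(win$chrom, IRanges::IRanges(win$start, win$end))
  count_cat <- function(cat) {
    s <- if (is.null(cat)) sites else sites[category == cat]
    if (!nrow(s)) return(integer(length(wgr)))
    sgr <- GenomicRanges::GRanges(s$chrom, IRanges::IRanges(s$pos, s$pos))
    GenomicRanges::countOverlaps(wgr, sgr)
  }
  win[, n_total := count_cat(NULL)]
  win[, n_donor := count_cat("donor")]
  win[, n_receptor := count_cat("receptor")]
  win[, n_het := count_cat("heterozygous")]
  win[, n_unknown := count_cat("unknown")]
  win[, donor_fraction := data.table::fifelse(n_total > 0, n_donor / n_total, NA_real_)]
  data.table::setattr(win, "window", window)
  data.table::setattr(win, "step", step)
  data.table::setattr(win, "class", c("window_track", class(win)))
  win[]
}

#' Call introgression blocks from a window track
#'
#' A block is a maximal run of at least `min_windows` consecutive windows in
#' which the chosen category's site fraction is at least `min_fraction` and
#' its site count at least `min_snps`. Runs are merged on genomic extent
#' (overlapping windows from the sliding step collapse into one block). When
#' the per-site table is supplied, block boundaries are clipped to the
#' outermost category SNP inside the qualifying extent and the site count is
#' re-counted from the sites rather than the windows.
#'
#' @param track a `window_track` from [windowed_density()].
#' @param min_fraction minimum category fraction per qualifying window.
#' @param min_snps minimum category site count per qualifying window (and,
#'   when `table` is given, per reported block).
#' @param min_windows minimum run length in windows.
#' @param category `"donor"` or `"unknown"` — which origin to segment.
#' @param table optional `trio_origin_table` (or its `sites`) for boundary
#'   clipping and exact per-block site counts.
#' @return data.frame of blocks: chrom, start, end, n_snps, mean_fraction,
#'   category.
#' @export
call_blocks <- function(track, min_fraction = 0.5, min_snps = 10,
                        min_windows = 2, category = c("donor", "unknown"),
                        table = NULL) {
  category <- match.arg(category)
  if (min_fraction <= 0 || min_snps <= 0 || min_windows <= 0)
    stopf("thresholds must be positive")
  tr <- data.table::as.data.table(track)
  n_cat <- if (category == "donor") tr$n_donor else tr$n_unknown
  frac <- ifelse(tr$n_total > 0, n_cat / tr$n_total, NA_real_)
  ok <- !is.na(frac) & frac >= min_fraction & n_cat >= min_snps

  sites <- NULL
  if (!is.null(table)) {
    s <- if (inherits(table, "trio_origin_table")) table$sites else
      data.table::as.data.table(table)
    keep <- s$category == category
    sites <- data.table::data.table(chrom = s$chrom[keep], pos = s$pos[keep])
  }

  blocks <- list()
  for (ch in unique(tr$chrom)) {
    idx <- which(tr$chrom == ch)
    idx <- idx[order(tr$start[idx])]
    r <- rle(ok[idx])
    ends_i <- cumsum(r$lengths)
    starts_i <- ends_i - r$lengths + 1L
    for (j in which(r$values & r$lengths >= min_windows)) {
      run <- idx[starts_i[j]:ends_i[j]]
      b_start <- min(tr$start[run]); b_end <- max(tr$end[run])
      n_b <- sum((if (category == "donor") tr$n_donor else tr$n_unknown)[run])
      if (!is.null(sites)) {
        in_b <- sites[chrom == ch & pos >= b_start & pos <= b_end]
        if (nrow(in_b) < min_snps) next
        b_start <- min(in_b$pos); b_end <- max(in_b$pos)
        n_b <- nrow(in_b)
      }
      blocks[[length(blocks) + 1L]] <- data.frame(
        chrom = ch, start = b_start, end = b_end, n_snps = n_b,
        mean_fraction = mean(frac[run]), category = category,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(blocks))
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      n_snps = numeric(), mean_fraction = numeric(),
                      category = character(), stringsAsFactors = FALSE))
  do.call(rbind, blocks)
}

#' Export a window track and block calls as bedGraph / BED
#'
#' Internal coordinates are 1-based inclusive; files are written in the
#' standard 0-based half-open browser convention. The bedGraph holds the
#' donor fraction per window (windows with no sites are omitted); the BED
#' holds the called blocks.
#'
#' @param track a `window_track`.
#' @param blocks data.frame from [call_blocks()].
#' @param bedgraph_path,bed_path output paths (NULL to skip either).
#' @return invisibly, a list of the written paths.
#' @export
export_tracks <- function(track, blocks, bedgraph_path = NULL, bed_path = NULL) {
  if (!is.null(bedgraph_path)) {
    tr <- data.table::as.data.table(track)[!is.na(donor_fraction)]
    gr <- GenomicRanges::GRanges(tr$chrom, IRanges::IRanges(tr$start, tr$end),
                                 score = tr$donor_fraction)
    rtracklayer::export(gr, bedgraph_path, format = "bedGraph")
  }
  if (!is.null(bed_path)) {
    if (nrow(blocks)) {
      gr <- GenomicRanges::GRanges(blocks$chrom,
                                   IRanges::IRanges(blocks$start, blocks$end))
      names(gr) <- sprintf("%s_block_%d", blocks$category, seq_len(nrow(blocks)))
      rtracklayer::export(gr, bed_path, format = "BED")
    } else {
      writeLines("# no blocks called", bed_path)
    }
  }
  invisible(list(bedgraph = bedgraph_path, bed = bed_path))
}
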