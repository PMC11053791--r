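#' Read one sample's calls from a VCF file
#'
#' Parses a VCF 4.2 file (via \pkg{vcfR}) into a [callset()] for the named
#' sample. Multi-allelic records are split into one biallelic record per
#' alternate allele at read time, so downstream trio logic only ever sees
#' biallelic records. Records with no usable GT for the sample get genotype
#' `"missing"`. The six quality annotations (QD, MQ, FS, SOR, MQRankSum,
#' ReadPosRankSum) are lifted from INFO when present.
#'
#' @param path VCF file path.
#' @param sample sample name; defaults to the only sample in the file.
#' @return a [callset()], sorted by (chrom, pos).
#' @export
read_callset <- function(path, sample = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  samples <- colnames(v@gt)[-1]
  if (is.null(sample)) {
    if (length(samples) != 1L)
      stopf("sample must be given when the VCF has %d samples (available: %s)",
            length(samples), paste(samples, collapse = ", "))
    sample <- samples[1]
  }
  if (!sample %in% samples)
    stopf("sample '%s' not in VCF; available samples: %s",
          sample, paste(samples, collapse = ", "))

  ref_name <- sub("^##reference=", "", grep("^##reference=", v@meta, value = TRUE)[1])
  if (is.na(ref_name)) ref_name <- "unknown"

  n <- nrow(fix)
  if (n == 0L) return(callset(sample, ref_name, empty_records()))

  gt_raw <- vcfR::extract.gt(v, element = "GT")[, sample]
  info <- lapply(INFO_KEYS, function(k)
    suppressWarnings(vcfR::extract.info(v, element = k, as.numeric = TRUE)))
  names(info) <- INFO_KEYS

  chrom <- fix[, "CHROM"]
  pos <- as.numeric(fix[, "POS"])
  ref <- fix[, "REF"]
  alt_field <- fix[, "ALT"]

  # split multi-allelic rows: one biallelic record per ALT allele
  alts <- strsplit(alt_field, ",", fixed = TRUE)
  n_alt <- lengths(alts)
  row_idx <- rep.int(seq_len(n), n_alt)
  alt_idx <- unlist(lapply(n_alt, seq_len), use.names = FALSE)

  gt_counts <- allele_counts(gt_raw)  # list of integer allele vectors or NULL
  genotype <- mapply(function(i, a) {
    al <- gt_counts[[i]]
    if (is.null(al)) return("missing")
    k <- sum(al == a)
    if (k >= 2L) "hom_alt" else if (k == 1L) "het" else "hom_ref"
  }, row_idx, alt_idx)

  rec <- data.table::data.table(
    chrom = chrom[row_idx], pos = pos[row_idx],
    ref = ref[row_idx], alt = unlist(alts, use.names = FALSE),
    genotype = genotype
  )
  for (k in INFO_KEYS) {
    vals <- info[[k]][row_idx]
    if (any(!is.na(vals))) rec[, (k) := vals]
  }
  if (is.unsorted(order(rec$chrom, rec$pos)))
    warnf("VCF '%s' is unsorted; records re-sorted", path)
  callset(sample, ref_name, rec)
}

# parse GT strings ("0/1", "1|2", "./.") into integer allele vectors; NULL if missing
allele_counts <- function(gt) {
  lapply(gt, function(g) {
    if (is.na(g) || g %in% c(".", "./.", ".|.")) return(NULL)
    al <- strsplit(g, "[/|]")[[1]]
    if (any(al == ".")) return(NULL)
    as.integer(al)
  })
}

empty_records <- function() {
  data.table::data.table(chrom = character(), pos = numeric(),
                         ref = character(), alt = character(),
                         genotype = character())
}

#' Write a call set to a minimal VCF 4.2 file
#'
#' Emits GT for the sample plus whichever of the six quality annotations are
#' present on each record as INFO keys. Reading the file back with
#' [read_callset()] reconstructs the call set exactly.
#'
#' @param cs a [callset()].
#' @param path output file path.
#' @param genome optional [genome_index()]; when given, contig header lines
#'   are written.
#' @return `path`, invisibly.
#' @export
write_callset <- function(cs, path, genome = NULL) {
  stopifnot(inherits(cs, "callset"))
  rec <- cs$records
  hdr <- c(
    "##fileformat=VCFv4.2",
    sprintf("##reference=%s", cs$reference_name),
    if (!is.null(genome))
      sprintf("##contig=<ID=%s,length=%d>", genome$chrom, as.integer(genome$length)),
    sprintf("##INFO=<ID=%s,Number=1,Type=Float,Description=\"%s\">",
            INFO_KEYS, c("Quality by depth", "RMS mapping quality",
                         "FisherStrand phred p-value", "Symmetric odds ratio",
                         "Mapping quality rank sum", "Read position rank sum")),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", cs$sample_id), collapse = "\t")
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  if (nrow(rec)) {
    present <- intersect(INFO_KEYS, names(rec))
    info_str <- rep(".", nrow(rec))
    if (length(present)) {
      parts <- lapply(present, function(k) {
        v <- rec[[k]]
        ifelse(is.na(v), NA_character_, sprintf("%s=%s", k, formatC(v, format = "g")))
      })
      info_str <- apply(do.call(cbind, parts), 1L, function(p) {
        p <- p[!is.na(p)]
        if (length(p)) paste(p, collapse = ";") else "."
      })
    }
    gt_str <- c(hom_ref = "0/0", het = "0/1", hom_alt = "1/1",
                missing = "./.")[rec$genotype]
    writeLines(paste(rec$chrom, format(rec$pos, scientific = FALSE, trim = TRUE),
                     ".", rec$ref, rec$alt, ".", ".", info_str, "GT", gt_str,
                     sep = "\t"), con)
  }
  invisible(path)
}

#' Remove records failing fixed quality thresholds
#'
#' Per-record hard filtering of variant calls on their quality annotations,
#' with the conventional default expression
#' `QD < 2.0 || MQ < 40.0 || FS > 60.0 || SOR > 3.0 || MQRankSum < -12.5 ||
#' ReadPosRankSum < -8.0`: QD, MQ, MQRankSum and ReadPosRankSum are lower
#' bounds, FS and SOR are upper bounds. A record is removed iff any annotation
#' it actually carries violates its threshold; absent annotations never fail a
#' record.
#'
#' @param cs a [callset()].
#' @param thresholds named list overriding any of the six defaults; unknown
#'   names are an error.
#' @return the filtered `callset` (a subset of the input; idempotent).
#' @export
#' @examples
#' rec <- data.frame(chrom = "chr1", pos = 1:2, ref = "A", alt = "G",
#'                   genotype = "hom_alt", QD = c(10, 1.9))
#' length(hard_filter(callset("s", "ref", rec)))  # 1
hard_filter <- function(cs, thresholds = list()) {
  defaults <- list(QD = 2.0, MQ = 40.0, FS = 60.0, SOR = 3.0,
                   MQRankSum = -12.5, ReadPosRankSum = -8.0)
  unknown <- setdiff(names(thresholds), names(defaults))
  if (length(unknown))
    stopf("unknown threshold key(s): %s (known: %s)",
          paste(unknown, collapse = ", "), paste(names(defaults), collapse = ", "))
  thr <- utils::modifyList(defaults, thresholds)
  lower <- c("QD", "MQ", "MQRankSum", "ReadPosRankSum")

  rec <- cs$records
  if (!nrow(rec)) return(cs)
  fail <- rep(FALSE, nrow(rec))
  for (k in INFO_KEYS) {
    if (!k %in% names(rec)) next
    v <- rec[[k]]
    bad <- if (k %in% lower) v < thr[[k]] else v > thr[[k]]
    fail <- fail | (!is.na(v) & bad)
  }
  callset(cs$sample_id, cs$reference_name, rec[!fail])
}
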