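#' Construct a KASP fluorescence plate
#'
#' @param wells data.frame with columns `well`, `sample_id`, `fam`, `hex`,
#'   `rox` (raw endpoint intensities, all >= 0).
#' @param marker_id marker assayed on the plate.
#' @return a `fluorescence_plate` object.
#' @export
fluorescence_plate <- function(wells, marker_id) {
  w <- data.table::as.data.table(wells)
  need <- c("well", "sample_id", "fam", "hex", "rox")
  miss <- setdiff(need, names(w))
  if (length(miss)) stopf("wells lack column(s): %s", paste(miss, collapse = ", "))
  if (!nrow(w)) stopf("plate has no wells")
  if (any(w$fam < 0 | w$hex < 0 | w$rox < 0)) stopf("intensities must be >= 0")
  structure(list(wells = w, marker_id = as.character(marker_id)),
            class = "fluorescence_plate")
}

#' @export
print.fluorescence_plate <- function(x, ...) {
  cat(sprintf("fluorescence_plate '%s': %d wells\n", x$marker_id, nrow(x$wells)))
  invisible(x)
}

#' Read a plate CSV (well,sample,marker,FAM,HEX,ROX)
#'
#' @param path CSV path; case-insensitive column names.
#' @return a [fluorescence_plate()]; the marker is taken from the `marker`
#'   column (must be unique per file).
#' @export
read_plate_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  names(d) <- tolower(names(d))
  need <- c("well", "sample", "marker", "fam", "hex", "rox")
  miss <- setdiff(need, names(d))
  if (length(miss)) stopf("plate CSV lacks column(s): %s", paste(miss, collapse = ", "))
  mk <- unique(d$marker)
  if (length(mk) != 1L) stopf("plate CSV mixes markers: %s", paste(mk, collapse = ", "))
  fluorescence_plate(
    data.frame(well = d$well, sample_id = d$sample,
               fam = d$fam, hex = d$hex, rox = d$rox),
    marker_id = mk)
}

#' Write a plate to CSV
#'
#' @param plate a [fluorescence_plate()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_plate_csv <- function(plate, path) {
  d <- data.frame(well = plate$wells$well, sample = plate$wells$sample_id,
                  marker = plate$marker_id, FAM = plate$wells$fam,
                  HEX = plate$wells$hex, ROX = plate$wells$rox)
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' ROX-normalise a fluorescence plate
#'
#' Computes x = FAM/ROX and y = HEX/ROX per well — the dye-ratio coordinates
#' genotypes cluster in — and flags wells whose normalised magnitude
#' `sqrt(x^2 + y^2)` falls below `signal_threshold` (no-template wells and
#' failed reactions), as well as wells with ROX = 0 where normalisation is
#' impossible.
#'
#' @param plate a [fluorescence_plate()].
#' @param signal_threshold normalised magnitude below which a well is flagged
#'   low-signal.
#' @return data.frame of well, sample_id, x, y, magnitude, low_signal.
#' @export
normalize_plate <- function(plate, signal_threshold = 0.2) {
  stopifnot(inherits(plate, "fluorescence_plate"))
  w <- plate$wells
  ok <- w$rox > 0
  x <- ifelse(ok, w$fam / w$rox, NA_real_)
  y <- ifelse(ok, w$hex / w$rox, NA_real_)
  mag <- sqrt(x^2 + y^2)
  data.frame(well = w$well, sample_id = w$sample_id, x = x, y = y,
             magnitude = mag,
             low_signal = !ok | mag < signal_threshold,
             stringsAsFactors = FALSE)
}

#' Call genotypes from normalised plate coordinates
#'
#' Clusters the non-low-signal wells on the angle `theta = atan2(y, x)` of
#' their dye-ratio coordinates. The number of clusters is chosen between 1 and
#' `k_expected` by average silhouette width (a single cluster is used when the
#' angular spread is negligible), with deterministic quantile-spread k-means
#' initialisation. The cluster with the smallest mean angle is the
#' FAM-homozygote (`allele1_hom`), the largest the HEX-homozygote
#' (`allele2_hom`), and the middle one (when three clusters are found) the
#' heterozygote. Per-well confidence is `1 - d_own / d_other` where `d_own`
#' and `d_other` are angular distances to the assigned and nearest other
#' centroid; wells below `min_confidence`, and all low-signal wells, are
#' `no_call`. Calls are invariant under uniform scaling of all intensities.
#'
#' @param norm output of [normalize_plate()].
#' @param marker_id marker name stamped on the calls.
#' @param k_expected maximum number of genotype clusters (2 or 3).
#' @param min_confidence wells with lower confidence become `no_call`.
#' @return data.frame of sample_id, marker_id, well, call, normalized_x,
#'   normalized_y, confidence.
#' @export
call_genotypes <- function(norm, marker_id = "marker", k_expected = 3,
                           min_confidence = 0.1) {
  stopifnot(k_expected %in% 2:3)
  out <- data.frame(sample_id = norm$sample_id, marker_id = marker_id,
                    well = norm$well, call = "no_call",
                    normalized_x = norm$x, normalized_y = norm$y,
                    confidence = 0, stringsAsFactors = FALSE)
  ok <- which(!norm$low_signal)
  if (length(ok) < k_expected) {
    warnf("only %d usable wells for %d expected clusters; all wells no_call",
          length(ok), k_expected)
    return(out)
  }
  theta <- atan2(norm$y[ok], norm$x[ok])
  k <- choose_k(theta, k_expected)
  if (k == 1L) {
    cl <- rep(1L, length(theta))
    centers <- mean(theta)
    conf <- rep(1, length(theta))
  } else {
    km <- kmeans_theta(theta, k)
    cl <- km$cluster
    centers <- km$centers
    d <- abs(outer(theta, centers, "-"))
    d_own <- d[cbind(seq_along(theta), cl)]
    # nearest other centroid: smallest distance excluding the assigned one
    d_other <- vapply(seq_along(theta), function(i) min(d[i, -cl[i]]), 0)
    conf <- pmax(0, 1 - d_own / d_other)
  }
  labels <- cluster_labels(centers, theta, norm$x[ok], cl)
  call <- labels[cl]
  call[conf < min_confidence] <- "no_call"
  out$call[ok] <- call
  out$confidence[ok] <- conf
  out
}

# exact 1-D k-means on angles: optimal contiguous partition of the sorted
# values by dynamic programming (deterministic, no initialisation sensitivity)
kmeans_theta <- function(theta, k) {
  n <- length(theta)
  o <- order(theta)
  xs <- theta[o]
  cs <- cumsum(xs); cs2 <- cumsum(xs^2)
  ss <- function(i, j) {
    s <- cs[j] - if (i > 1L) cs[i - 1L] else 0
    s2 <- cs2[j] - if (i > 1L) cs2[i - 1L] else 0
    max(0, s2 - s^2 / (j - i + 1L))
  }
  D <- matrix(Inf, k, n); B <- matrix(0L, k, n)
  for (j in seq_len(n)) { D[1, j] <- ss(1L, j); B[1, j] <- 1L }
  if (k > 1L) for (m in 2:k) for (j in m:n) for (i in m:j) {
    v <- D[m - 1L, i - 1L] + ss(i, j)
    if (v < D[m, j]) { D[m, j] <- v; B[m, j] <- i }
  }
  cl_sorted <- integer(n); j <- n
  for (m in k:1) { i <- B[m, j]; cl_sorted[i:j] <- m; j <- i - 1L }
  cl <- integer(n); cl[o] <- cl_sorted
  centers <- vapply(seq_len(k), function(m) mean(theta[cl == m]), 0)
  list(cluster = cl, centers = centers)
}

# k selection by average silhouette width over 2..k_max; a best silhouette
# below 0.7 (or negligible angular spread) means one cluster
choose_k <- function(theta, k_max) {
  if (diff(range(theta)) < 0.1 || length(unique(theta)) < 2L) return(1L)
  ks <- 2:min(k_max, length(unique(theta)))
  sil <- vapply(ks, function(k) {
    km <- kmeans_theta(theta, k)
    if (length(unique(km$cluster)) < k) return(-Inf)
    mean(cluster::silhouette(km$cluster, stats::dist(theta))[, "sil_width"])
  }, 0)
  if (max(sil) < 0.7) 1L else ks[which.max(sil)]
}

# order clusters by mean angle; FAM axis (small theta) = allele1
cluster_labels <- function(centers, theta, x, cl) {
  mean_x <- vapply(seq_along(centers), function(j) mean(x[cl == j]), 0)
  ord <- order(centers, -mean_x)   # tie on angle broken by x-coordinate
  lab <- character(length(centers))
  if (length(centers) == 1L) {
    # a lone cluster is labelled by its absolute angle
    lab[ord] <- if (centers[ord] < pi / 6) "allele1_hom"
                else if (centers[ord] > pi / 3) "allele2_hom" else "het"
  }
  if (length(centers) == 2L) lab[ord] <- c("allele1_hom", "allele2_hom")
  if (length(centers) == 3L) lab[ord] <- c("allele1_hom", "het", "allele2_hom")
  lab
}

#' Summarise mutant-haplotype carriers across a marker panel
#'
#' Given genotype calls for a panel of varieties over several KASP markers
#' (e.g. the four herbicide-tolerance mutations A179V, W548M, S627N, G628E),
#' labels each variety with the mutant haplotype(s) it carries homozygously
#' and reports per-marker carrier frequency as a percentage of the panel.
#' Inbred panels are screened homozygous, so heterozygous calls are not
#' counted as carriers unless `include_het = TRUE`. Conflicting duplicate
#' wells for one variety yield `no_call` for that variety (with a warning).
#'
#' @param calls data.frame from [call_genotypes()] (rows from several markers
#'   may be concatenated); columns sample_id, marker_id, call.
#' @param mutant_call which call state carries the mutant allele
#'   (`"allele2_hom"` by convention: the HEX-coupled allele-specific primer
#'   carries the mutation).
#' @param include_het also count heterozygous calls as carriers.
#' @return list with `haplotypes` (variety x marker carrier table) and
#'   `frequency` (marker, carriers, total, frequency_pct to 2 decimals).
#' @export
summarize_panel <- function(calls, mutant_call = "allele2_hom",
                            include_het = FALSE) {
  d <- data.table::as.data.table(calls)[, .(sample_id, marker_id, call)]
  markers <- unique(d$marker_id)
  varieties <- unique(d$sample_id)
  cov <- d[, .N, by = .(sample_id, marker_id)]
  full <- data.table::CJ(sample_id = varieties, marker_id = markers)
  if (nrow(cov[full, on = c("sample_id", "marker_id")][is.na(N)]))
    stopf("every variety must have a call for every marker")

  # duplicate wells: consistent -> that call; conflicting -> no_call
  resolved <- d[, {
    u <- unique(call)
    if (length(u) > 1L) {
      list(call = "no_call", conflict = TRUE)
    } else list(call = u, conflict = FALSE)
  }, by = .(sample_id, marker_id)]
  if (any(resolved$conflict))
    warnf("%d variety/marker pair(s) had conflicting duplicate wells; set to no_call",
          sum(resolved$conflict))

  carrier_states <- c(mutant_call, if (include_het) "het")
  resolved[, carrier := call %in% carrier_states]
  hap <- data.table::dcast(resolved, sample_id ~ marker_id, value.var = "carrier")
  freq <- resolved[, .(carriers = sum(carrier), total = length(varieties)),
                   by = .(marker = marker_id)]
  freq[, frequency_pct := round_half_up(100 * carriers / total, 2)]
  list(haplotypes = as.data.frame(hap), frequency = as.data.frame(freq))
}

#' Scatter plot of plate calls in dye-ratio space
#'
#' @param calls output of [call_genotypes()].
#' @param ... passed to [graphics::plot()].
#' @return invisibly, `calls`.
#' @export
plot_plate_calls <- function(calls, ...) {
  cols <- c(allele1_hom = "dodgerblue3", het = "seagreen",
            allele2_hom = "firebrick3", no_call = "grey60")
  graphics::plot(calls$normalized_x, calls$normalized_y,
                 col = cols[calls$call], pch = 19,
                 xlab = "FAM / ROX", ylab = "HEX / ROX",
                 main = unique(calls$marker_id)[1], ...)
  graphics::legend("topright", legend = names(cols), col = cols, pch = 19,
                   bty = "n")
  invisible(calls)
}
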