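#' Round half away from zero
#'
#' Fixed-point rounding where .5 always rounds up in magnitude, the convention
#' used for the reported percentage tables (base R's `round()` rounds half to
#' even, which turns 0.125 into 0.12 rather than 0.13).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded to `digits` decimals.
#' @export
#' @examples
#' round_half_up(12.745, 2)  # 12.75, where round() gives 12.74
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Deterministic substream seed for component `k` under global seed `seed`.
# Kept below 2^31 so it is always a valid R integer.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1103L + as.numeric(k) * 12007L) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

DNA_BASES <- c("A", "C", "G", "T")

random_dna <- function(n) paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

gc_fraction <- function(x) {
  b <- strsplit(x, "")[[1]]
  sum(b %in% c("G", "C")) / length(b)
}
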