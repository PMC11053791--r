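#' Built-in restriction enzymes
#'
#' A small editable table of palindromic type II enzymes used for CAPS marker
#' design. `motif` is the IUPAC recognition sequence and `cut_offset` the
#' number of bases after the motif start at which the top strand is cut
#' (HinfI G^ANTC has offset 1). All built-ins have palindromic recognition
#' sites, so a forward-strand scan finds every site.
#'
#' @return data.frame with columns name, motif, cut_offset.
#' @export
restriction_enzymes <- function() {
  data.frame(
    name = c("HinfI", "EcoRI", "AluI", "DdeI", "HaeIII", "MseI", "TaqI"),
    motif = c("GANTC", "GAATTC", "AGCT", "CTNAG", "GGCC", "TTAA", "TCGA"),
    cut_offset = c(1L, 1L, 2L, 1L, 2L, 1L, 1L),
    stringsAsFactors = FALSE)
}

# resolve an enzyme argument (name, "G^ANTC" string, or list) to motif+offset
resolve_enzyme <- function(enzyme) {
  tab <- restriction_enzymes()
  if (is.list(enzyme)) {
    stopifnot(!is.null(enzyme$motif), !is.null(enzyme$cut_offset))
    return(list(name = enzyme$name %||% "custom",
                motif = toupper(enzyme$motif),
                cut_offset = as.integer(enzyme$cut_offset)))
  }
  enzyme <- as.character(enzyme)
  if (grepl("^", enzyme, fixed = TRUE)) {
    caret <- regexpr("^", enzyme, fixed = TRUE)
    return(list(name = "custom", motif = toupper(gsub("^", "", enzyme, fixed = TRUE)),
                cut_offset = as.integer(caret - 1L)))
  }
  i <- match(enzyme, tab$name)
  if (is.na(i))
    stopf("unknown enzyme '%s'; built-ins: %s", enzyme,
          paste(tab$name, collapse = ", "))
  list(name = tab$name[i], motif = tab$motif[i], cut_offset = tab$cut_offset[i])
}

#' In-silico restriction digest of an amplicon
#'
#' Finds recognition sites (IUPAC-aware) and cuts the sequence to completion.
#' Motif self-overlaps are resolved leftmost-first: a site is only cut if no
#' earlier cut already falls inside its span, matching physical digestion
#' where cutting one of two overlapping sites destroys the other. Fragment
#' lengths always partition the amplicon and sum to its length.
#'
#' @param amplicon DNA sequence (character).
#' @param enzyme a built-in enzyme name (see [restriction_enzymes()]), a
#'   motif string with `^` marking the cut (e.g. `"G^ANTC"`), or a
#'   `list(motif=, cut_offset=)`.
#' @return integer vector of fragment lengths, 5' to 3'.
#' @export
#' @examples
#' insilico_digest(paste0(strrep("A", 100), "GACTC", strrep("T", 115)), "HinfI")
insilico_digest <- function(amplicon, enzyme) {
  e <- resolve_enzyme(enzyme)
  L <- nchar(amplicon)
  k <- nchar(e$motif)
  starts <- sort(motif_matches(amplicon, e$motif))
  cuts <- integer(0)
  last_cut <- -1L
  for (s in starts) {
    # a previous cut strictly inside this site's span destroyed it
    if (last_cut >= s && last_cut <= s + k - 2L) next
    cut_after <- s + e$cut_offset - 1L
    if (cut_after >= 1L && cut_after <= L - 1L) {
      cuts <- c(cuts, cut_after)
      last_cut <- cut_after
    }
  }
  as.integer(diff(c(0L, cuts, L)))
}
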