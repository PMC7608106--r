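# IUPAC nucleotide ambiguity algebra. The code -> base-set map is taken
# from Biostrings::IUPAC_CODE_MAP; only the gap character is added locally.

.DNA_LETTERS <- c("A", "C", "G", "T")

#' IUPAC base sets
#'
#' The set of concrete bases denoted by each IUPAC nucleotide symbol
#' (A, C, G, T; R = A/G; Y = C/T; S = G/C; W = A/T; K = G/T; M = A/C;
#' B = not A; D = not C; H = not G; V = not T; N = any).
#'
#' @param symbols character vector of single IUPAC symbols.
#' @return a named list of character vectors of concrete bases.
#' @examples
#' iupacBases(c("H", "Y", "N"))
#' @export
iupacBases <- function(symbols) {
  map <- Biostrings::IUPAC_CODE_MAP
  bad <- setdiff(unique(symbols), names(map))
  if (length(bad))
    fmValidationError(paste0("not an IUPAC nucleotide symbol: ",
                             paste(bad, collapse = ", ")))
  lapply(setNames(symbols, symbols), function(s) chars(map[[s]]))
}

# inverse map: sorted base-set string (e.g. "ACT") -> symbol ("H")
.IUPAC_INVERSE <- local({
  map <- Biostrings::IUPAC_CODE_MAP
  setNames(names(map),
           vapply(map, function(s)
             paste0(sort(strsplit(s, "")[[1L]]), collapse = ""), ""))
})

iupacSymbolFor <- function(bases) {
  key <- collapse0(sort(unique(bases)))
  sym <- .IUPAC_INVERSE[key]
  if (is.na(sym))
    fmValidationError(paste0("no IUPAC symbol for base set {", key, "}"))
  unname(sym)
}

#' Per-symbol degeneracy of a degenerate oligonucleotide
#'
#' @param oligo a DNA-IUPAC string (no gaps).
#' @return the product of per-position base-set sizes.
#' @examples
#' oligoDegeneracy("AYN")  # 1 * 2 * 4 = 8
#' @export
oligoDegeneracy <- function(oligo) {
  validateSeq(oligo, "DNA", allowGap = FALSE, what = "oligo")
  prod(lengths(iupacBases(chars(oligo))))
}

#' Expand a degenerate oligo into its concrete sequences
#'
#' A degenerate (IUPAC-ambiguous) primer denotes the set of concrete
#' oligos obtained by substituting every ambiguity symbol with each base
#' in its set; the set size is the primer's degeneracy.
#'
#' @param oligo a DNA-IUPAC string.
#' @param cap refuse expansion if the degeneracy exceeds this.
#' @return character vector of concrete DNA strings.
#' @examples
#' expandDegenerate("AY")   # "AC" "AT"
#' expandDegenerate("ACGT") # itself
#' @export
expandDegenerate <- function(oligo, cap = 4096L) {
  validateSeq(oligo, "DNA", allowGap = FALSE, what = "oligo")
  sets <- iupacBases(chars(oligo))
  deg <- prod(lengths(sets))
  if (deg > cap)
    fmValidationError(sprintf(
      "degeneracy %d exceeds cap %d; refusing to expand", deg, as.integer(cap)))
  if (length(sets) == 0L) return(character(0))
  grid <- expand.grid(rev(sets), KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  sort(apply(grid[, rev(seq_along(sets)), drop = FALSE], 1L, collapse0))
}

#' Reverse complement of a DNA-IUPAC string
#'
#' IUPAC-aware: the complement of an ambiguity symbol is the symbol whose
#' base set is the complement of each member (e.g. H, "not G", maps to D,
#' "not C"). Gaps are rejected; use only on ungapped sequence.
#'
#' @param seq a DNA-IUPAC string or character vector of them.
#' @return reverse complement(s), same length as the input.
#' @examples
#' revComp("AHG")  # "CDT"
#' @export
revComp <- function(seq) {
  for (s in seq) validateSeq(s, "DNA", allowGap = FALSE,
                             what = "sequence")
  unname(as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(seq))))
}
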