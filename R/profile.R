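# Per-column alignment profiles.

#' ColumnProfile: per-column composition of one alignment class
#'
#' Summarises an aligned sequence class column by column: symbol
#' frequencies over the non-gap symbols (summing to 1 wherever a column
#' has at least one non-gap symbol), the gap fraction, the consensus
#' (majority) symbol, and the conservation score, defined as the
#' frequency of the consensus symbol among non-gap symbols. Conservation
#' by majority frequency, rather than entropy, is directly thresholdable
#' and mirrors the visual conserved/distinct inspection it replaces.
#'
#' @slot freqs numeric matrix, symbols x columns; non-gap frequencies.
#' @slot gapFraction numeric vector in `[0, 1]`, one per column.
#' @slot consensus character vector of consensus symbols (`-` for an
#'   all-gap column; ties broken alphabetically).
#' @slot conservation numeric vector in `[0, 1]`.
#' @slot nseq number of sequences profiled.
#' @slot alphabet `"DNA"` or `"protein"`.
#' @exportClass ColumnProfile
setClass("ColumnProfile",
  representation(freqs = "matrix", gapFraction = "numeric",
                 consensus = "character", conservation = "numeric",
                 nseq = "integer", alphabet = "character"))

setValidity("ColumnProfile", function(object) {
  nc <- ncol(object@freqs)
  if (length(object@gapFraction) != nc || length(object@consensus) != nc ||
      length(object@conservation) != nc)
    return("per-column slots must all have length ncol(freqs)")
  sums <- colSums(object@freqs)
  nongap <- object@gapFraction < 1
  if (any(abs(sums[nongap] - 1) > 1e-9))
    return("non-gap frequencies must sum to 1 in every non-empty column")
  if (any(object@gapFraction < 0 | object@gapFraction > 1))
    return("gapFraction outside [0, 1]")
  if (any(object@conservation < 0 | object@conservation > 1))
    return("conservation outside [0, 1]")
  TRUE
})

setMethod("show", "ColumnProfile", function(object) {
  cat(sprintf("ColumnProfile: %d columns, %d sequences (%s)\n",
              ncol(object@freqs), object@nseq, object@alphabet))
  cat(sprintf("  mean conservation %.3f, mean gap fraction %.3f\n",
              mean(object@conservation), mean(object@gapFraction)))
})

#' @describeIn buildProfile number of columns in a profile.
#' @param x a `ColumnProfile`.
#' @export
profileLength <- function(x) ncol(x@freqs)

#' @describeIn buildProfile per-column conservation scores.
#' @export
conservation <- function(x) x@conservation

#' @describeIn buildProfile per-column gap fractions.
#' @export
gapFraction <- function(x) x@gapFraction

#' @describeIn buildProfile per-column consensus symbols.
#' @export
consensus <- function(x) x@consensus

#' @describeIn buildProfile frequency of symbol `sym` at column `col`
#'   (0 when the symbol was never observed there).
#' @param sym single symbol; `col` column index.
#' @param col integer column index.
#' @export
symbolFreq <- function(x, sym, col) {
  i <- match(sym, rownames(x@freqs))
  if (is.na(i)) return(rep(0, length(col)))
  unname(x@freqs[i, col])
}

#' Build a per-column profile of an aligned sequence class
#'
#' @param alignment a named `XStringSet` or character vector of aligned
#'   (equal-length) sequences of one class; at least two sequences.
#' @param alphabet `"DNA"` or `"protein"`.
#' @return a [ColumnProfile-class] object with one entry per column.
#' @examples
#' p <- buildProfile(c(a = "ACGT", b = "ACGA"))
#' conservation(p)  # 1 1 1 0.5
#' @export
buildProfile <- function(alignment, alphabet = c("DNA", "protein")) {
  alphabet <- match.arg(alphabet)
  seqs <- toupper(asNamedChar(alignment))
  if (length(seqs) < 2L)
    fmValidationError("an alignment profile needs at least 2 sequences")
  w <- nchar(seqs)
  if (length(unique(w)) != 1L) {
    bad <- names(seqs)[which(w != w[1L])[1L]]
    if (is.null(bad) || is.na(bad)) bad <- which(w != w[1L])[1L]
    fmValidationError(sprintf(
      "ragged alignment: record '%s' has length %d, expected %d",
      bad, w[w != w[1L]][1L], w[1L]))
  }
  for (i in seq_along(seqs))
    validateSeq(seqs[i], alphabet, allowGap = TRUE,
                what = sprintf("record '%s'", names(seqs)[i]))
  mat <- matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
                nrow = length(seqs), byrow = TRUE)
  nc <- ncol(mat)
  syms <- sort(setdiff(unique(as.vector(mat)), "-"))
  counts <- vapply(seq_len(nc), function(j) {
    tabulate(match(mat[, j], syms), nbins = length(syms))
  }, numeric(length(syms)))
  counts <- matrix(counts, nrow = length(syms),
                   dimnames = list(syms, NULL))
  nongap <- colSums(counts)
  gapFrac <- 1 - nongap / length(seqs)
  freqs <- sweep(counts, 2L, pmax(nongap, 1L), "/")
  consIdx <- apply(freqs, 2L, which.max)   # ties: alphabetically first row
  cons <- ifelse(nongap > 0, syms[consIdx], "-")
  consv <- ifelse(nongap > 0, freqs[cbind(consIdx, seq_len(nc))], 0)
  new("ColumnProfile", freqs = freqs, gapFraction = as.numeric(gapFrac),
      consensus = cons, conservation = as.numeric(consv),
      nseq = length(seqs), alphabet = alphabet)
}

#' Map an alignment column to an ungapped reference coordinate
#'
#' Converts alignment column indices to 1-based residue (or nucleotide)
#' indices on a named reference sequence, counting only its non-gap
#' symbols. When the reference itself is gapped at the queried column the
#' index of the nearest preceding non-gap position is returned and
#' flagged.
#'
#' @param alignment named aligned `XStringSet` or character vector.
#' @param referenceId id of the reference record.
#' @param column integer vector of 1-based alignment columns.
#' @return data.frame with `column`, `residue` (0 when no non-gap symbol
#'   precedes the column) and logical `onGap`.
#' @examples
#' mapColumnToReference(c(r = "A-CG"), "r", 3)  # residue 2
#' @export
mapColumnToReference <- function(alignment, referenceId, column) {
  seqs <- asNamedChar(alignment)
  if (!referenceId %in% names(seqs))
    fmLookupError(paste0("reference id not in alignment: ", referenceId))
  ref <- chars(toupper(seqs[[referenceId]]))
  if (any(column < 1L | column > length(ref)))
    fmValidationError("column index out of alignment bounds")
  cum <- cumsum(ref != "-")
  data.frame(column = as.integer(column),
             residue = cum[column],
             onGap = ref[column] == "-")
}

#' Map an ungapped reference residue to its alignment column
#'
#' Inverse of [mapColumnToReference()] for non-gap positions.
#'
#' @inheritParams mapColumnToReference
#' @param residue 1-based ungapped index on the reference.
#' @return integer alignment column(s).
#' @export
mapReferenceToColumn <- function(alignment, referenceId, residue) {
  seqs <- asNamedChar(alignment)
  if (!referenceId %in% names(seqs))
    fmLookupError(paste0("reference id not in alignment: ", referenceId))
  ref <- chars(toupper(seqs[[referenceId]]))
  pos <- which(ref != "-")
  if (any(residue < 1L | residue > length(pos)))
    fmValidationError("residue index beyond ungapped reference length")
  pos[residue]
}
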