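# Discriminative conserved windows ("far-red islands").

#' Find conserved windows that discriminate target from background
#'
#' Slides a fixed-length window over two class profiles built on one
#' merged alignment coordinate system and reports every window that is
#' conserved within the target class yet distinct from the background
#' class -- the "far-red island" criterion used to pick the forward
#' primer target. A window qualifies iff
#' \itemize{
#'   \item every column has target conservation >= `minTargetConservation`,
#'   \item every column has gap fraction <= `maxGapFraction` in both
#'     classes, and
#'   \item the fraction of columns whose target consensus differs from
#'     the background consensus is >= `minDiscrimCols`.
#' }
#' The discrimination score of a window is the mean over its columns of
#' `1 - (background frequency of the target consensus symbol)`; 1 means
#' the background never shows the target's consensus anywhere in the
#' window. Candidates are ranked by discrimination score, then by
#' within-target conservation (the minimum over window columns), ties
#' broken by leftmost start, so output order is fully deterministic.
#'
#' @param targetProfile,backgroundProfile [ColumnProfile-class] objects of
#'   equal length (classes of one merged alignment).
#' @param windowLen window length in columns (>= 6); defaults: 18 for DNA
#'   (the ~20 bp stretch a primer core covers), 6 for protein (the length
#'   of the VIPEDV motif).
#' @param minTargetConservation minimum per-column target conservation.
#' @param minDiscrimCols minimum fraction of consensus-different columns.
#' @param maxGapFraction maximum per-column gap fraction in either class.
#' @param referenceAlignment,referenceId optional: a named aligned set and
#'   the id of a reference record used to annotate candidates with
#'   1-based ungapped reference coordinates (`refStart`, `refEnd`).
#' @return data.frame of island candidates: `start`, `end`, `length`
#'   (alignment columns, 1-based inclusive), `targetConservation` (min
#'   over columns), `discrimScore`, and reference coordinates when a
#'   reference is supplied. Zero rows when no window qualifies.
#' @examples
#' t <- buildProfile(c(a = "AAAAAAAA", b = "AAAAAAAA"))
#' b <- buildProfile(c(c = "CCCCCCCC", d = "CCCCCCCC"))
#' discriminativeIslands(t, b, windowLen = 6)
#' @export
discriminativeIslands <- function(targetProfile, backgroundProfile,
                                  windowLen = if (targetProfile@alphabet ==
                                                  "DNA") 18L else 6L,
                                  minTargetConservation = 0.8,
                                  minDiscrimCols = 0.5,
                                  maxGapFraction = 0.2,
                                  referenceAlignment = NULL,
                                  referenceId = NULL) {
  nc <- profileLength(targetProfile)
  if (profileLength(backgroundProfile) != nc)
    fmValidationError("target and background profiles differ in length")
  if (windowLen < 6L)
    fmValidationError("'windowLen' must be at least 6")
  if (windowLen > nc)
    fmValidationError(sprintf(
      "window (%d) longer than alignment (%d columns)", windowLen, nc))

  tCons <- conservation(targetProfile)
  colOk <- tCons >= minTargetConservation &
    gapFraction(targetProfile) <= maxGapFraction &
    gapFraction(backgroundProfile) <= maxGapFraction
  tConsSym <- consensus(targetProfile)
  differs <- tConsSym != consensus(backgroundProfile)
  # background frequency of the target consensus symbol, per column
  bgOfTarget <- vapply(seq_len(nc), function(j)
    symbolFreq(backgroundProfile, tConsSym[j], j), 0)
  colScore <- 1 - bgOfTarget

  starts <- seq_len(nc - windowLen + 1L)
  rows <- lapply(starts, function(s) {
    idx <- s:(s + windowLen - 1L)
    if (!all(colOk[idx])) return(NULL)
    if (mean(differs[idx]) < minDiscrimCols) return(NULL)
    data.frame(start = s, end = s + windowLen - 1L, length = windowLen,
               targetConservation = min(tCons[idx]),
               discrimScore = mean(colScore[idx]))
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) {
    out <- data.frame(start = integer(0), end = integer(0),
                      length = integer(0), targetConservation = numeric(0),
                      discrimScore = numeric(0))
  } else {
    out <- do.call(rbind, rows)
    ord <- order(-out$discrimScore, -out$targetConservation, out$start)
    out <- out[ord, , drop = FALSE]
    rownames(out) <- NULL
  }
  if (!is.null(referenceAlignment) && !is.null(referenceId) && nrow(out)) {
    out$refStart <- mapColumnToReference(referenceAlignment, referenceId,
                                         out$start)$residue
    out$refEnd <- mapColumnToReference(referenceAlignment, referenceId,
                                       out$end)$residue
  }
  out
}
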