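# In-silico PCR: degenerate primer binding sites and amplicon prediction.
#
# Matching is IUPAC-intersection based: a primer position matches a
# template position iff their base sets intersect, so ambiguity in either
# is handled symmetrically. Sequences are encoded as 4-bit masks
# (A=1, C=2, G=4, T=8) and offsets are scanned with vectorised bit-ANDs.

.IUPAC_BITS <- local({
  bit <- c(A = 1L, C = 2L, G = 4L, T = 8L)
  map <- Biostrings::IUPAC_CODE_MAP
  vapply(map, function(s) sum(bit[strsplit(s, "")[[1L]]]), 0L)
})

.encodeBits <- function(seq) {
  v <- .IUPAC_BITS[chars(seq)]
  if (anyNA(v))
    fmValidationError("sequence contains a non-IUPAC symbol (gaps not allowed here)")
  unname(v)
}

# offsets (1-based) where core matches template with <= maxMismatch
# mismatches overall and 0 mismatches in the 3'-terminal clampLen core
# positions; returns data.frame(offset, mismatches)
.scanCore <- function(tmplBits, coreBits, maxMismatch, clampLen) {
  n <- length(tmplBits); m <- length(coreBits)
  if (m > n)
    return(data.frame(offset = integer(0), mismatches = integer(0)))
  nOff <- n - m + 1L
  mm <- integer(nOff)
  clampBad <- logical(nOff)
  clampFrom <- m - min(clampLen, m) + 1L
  for (j in seq_len(m)) {
    miss <- bitwAnd(tmplBits[j:(j + nOff - 1L)], coreBits[j]) == 0L
    mm <- mm + miss
    if (j >= clampFrom) clampBad <- clampBad | miss
  }
  keep <- which(mm <= maxMismatch & !clampBad)
  data.frame(offset = keep, mismatches = mm[keep])
}

#' Find degenerate-primer binding sites on a template
#'
#' Scans both strands of a template for positions where the primer core
#' matches with at most `maxMismatch` positions failing the
#' IUPAC-intersection test, requiring the `clampLen` 3'-terminal core
#' positions to match exactly (mismatches near the extending 3' end
#' abolish amplification in practice). The 5' tag is ignored: only the
#' core binds template-specifically. Coordinates are 1-based starts of
#' the core match on the plus strand; strand `-` means the reverse
#' complement of the core matches there (the primer binds the plus strand
#' and extends leftward).
#'
#' @param template one named sequence (named character or `DNAStringSet`
#'   element) or a named character vector of length 1.
#' @param primer a [DegeneratePrimer-class] (or an IUPAC core string).
#' @param maxMismatch tolerated mismatches outside the clamp (default 2).
#' @param clampLen 3'-clamp length requiring exact match (default 3).
#' @return data.frame of sites: `templateId`, `strand`, `start`,
#'   `mismatches`, `clampOk` (always `TRUE` for returned sites), sorted
#'   by coordinate. A core longer than the template yields zero rows.
#' @examples
#' findPrimerSites(c(t1 = "TTACGTAT"), "ACGTAT")  # one exact site at 3
#' @export
findPrimerSites <- function(template, primer, maxMismatch = 2L,
                            clampLen = 3L) {
  core <- if (is(primer, "DegeneratePrimer")) primerCore(primer)
          else toupper(primer)
  tmpl <- toupper(asNamedChar(template))
  tid <- names(tmpl)
  if (is.null(tid)) tid <- "template"
  tb <- .encodeBits(tmpl[[1L]])
  m <- nchar(core)
  fwd <- .scanCore(tb, .encodeBits(core), maxMismatch, clampLen)
  # minus strand: scan the reverse-complemented template, convert back
  rb <- rev(vapply(tb, function(x)
    bitwOr(bitwOr(ifelse(bitwAnd(x, 1L) > 0L, 8L, 0L),
                  ifelse(bitwAnd(x, 8L) > 0L, 1L, 0L)),
           bitwOr(ifelse(bitwAnd(x, 2L) > 0L, 4L, 0L),
                  ifelse(bitwAnd(x, 4L) > 0L, 2L, 0L))), 0L))
  rev_ <- .scanCore(rb, .encodeBits(core), maxMismatch, clampLen)
  n <- length(tb)
  out <- rbind(
    if (nrow(fwd)) data.frame(templateId = tid[1L], strand = "+",
                              start = fwd$offset,
                              mismatches = fwd$mismatches, clampOk = TRUE),
    if (nrow(rev_)) data.frame(templateId = tid[1L], strand = "-",
                               start = n - rev_$offset - m + 2L,
                               mismatches = rev_$mismatches, clampOk = TRUE))
  if (is.null(out))
    out <- data.frame(templateId = character(0), strand = character(0),
                      start = integer(0), mismatches = integer(0),
                      clampOk = logical(0))
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Predict amplicons of a primer pair on templates (in-silico PCR)
#'
#' Enumerates all convergent forward/reverse binding-site combinations --
#' the two sites on opposite strands, facing each other -- whose product
#' length (outermost bases of the two core matches, 1-based inclusive)
#' falls within `sizeBounds`. All qualifying amplicons are reported (no
#' nesting filter), sorted by length then coordinate; the sequence is
#' reported on the plus strand.
#'
#' @param templates named `DNAStringSet` or named character vector.
#' @param pair a [PrimerPair-class].
#' @param sizeBounds numeric `c(min, max)` product length in bp.
#' @param maxMismatch,clampLen see [findPrimerSites()].
#' @return data.frame: `templateId`, `start`, `end`, `length`,
#'   `sequence`.
#' @export
amplify <- function(templates, pair, sizeBounds = c(200, 5000),
                    maxMismatch = 2L, clampLen = 3L) {
  if (sizeBounds[1L] > sizeBounds[2L])
    fmValidationError("sizeBounds: min exceeds max")
  tmpl <- toupper(asNamedChar(templates))
  ids <- names(tmpl)
  if (is.null(ids)) ids <- as.character(seq_along(tmpl))
  out <- list()
  for (i in seq_along(tmpl)) {
    t1 <- setNames(tmpl[i], ids[i])
    fwS <- findPrimerSites(t1, pairForward(pair), maxMismatch, clampLen)
    rvS <- findPrimerSites(t1, pairReverse(pair), maxMismatch, clampLen)
    lenF <- nchar(primerCore(pairForward(pair)))
    lenR <- nchar(primerCore(pairReverse(pair)))
    # convergent: one site on +, the other on -, plus-site upstream
    combos <- rbind(
      .convergent(fwS, rvS, lenF, lenR),
      .convergent(rvS, fwS, lenR, lenF))
    if (is.null(combos) || !nrow(combos)) next
    combos$length <- combos$end - combos$start + 1L
    keep <- combos$length >= sizeBounds[1L] & combos$length <= sizeBounds[2L]
    combos <- combos[keep, , drop = FALSE]
    if (!nrow(combos)) next
    combos$templateId <- ids[i]
    combos$sequence <- substring(tmpl[i], combos$start, combos$end)
    out[[length(out) + 1L]] <- combos
  }
  if (!length(out))
    return(data.frame(templateId = character(0), start = integer(0),
                      end = integer(0), length = integer(0),
                      sequence = character(0)))
  res <- do.call(rbind, out)
  res <- res[order(res$length, res$templateId, res$start),
             c("templateId", "start", "end", "length", "sequence")]
  rownames(res) <- NULL
  unique(res)
}

# plus-strand site from `a`, minus-strand site from `b`, a upstream of b
.convergent <- function(a, b, lenA, lenB) {
  aP <- a[a$strand == "+", , drop = FALSE]
  bM <- b[b$strand == "-", , drop = FALSE]
  if (!nrow(aP) || !nrow(bM)) return(NULL)
  g <- expand.grid(i = seq_len(nrow(aP)), j = seq_len(nrow(bM)))
  start <- aP$start[g$i]
  end <- bM$start[g$j] + lenB - 1L
  keep <- end >= start + lenA  # convergent, non-degenerate span
  if (!any(keep)) return(NULL)
  data.frame(start = start[keep], end = end[keep])
}
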