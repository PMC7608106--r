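# Diagnostic-motif screening and far-red / white-light classification.

#' MotifModel: a short diagnostic protein motif with a match threshold
#'
#' Houses the far-red "VIPEDV-like" and white-light "ENACS-like"
#' signatures: a reference motif, per-position allowed residue sets
#' (defaulting to the reference residue alone), and the minimum number of
#' matching positions for a window to count as a hit. "Like" is
#' quantified as a count threshold: by default 5 of 6 positions for
#' VIPEDV and 4 of 5 for ENACS.
#'
#' @slot name motif name.
#' @slot motif reference motif (protein, length >= 4).
#' @slot allowed list of per-position allowed residue sets.
#' @slot minMatches minimum matching positions, at least half the length.
#' @exportClass MotifModel
setClass("MotifModel",
  representation(name = "character", motif = "character",
                 allowed = "list", minMatches = "integer"))

setValidity("MotifModel", function(object) {
  len <- nchar(object@motif)
  if (len < 4L) return("motif length must be >= 4")
  if (length(object@allowed) != len)
    return("'allowed' must have one residue set per motif position")
  if (object@minMatches < ceiling(len / 2) || object@minMatches > len)
    return("minMatches must lie in [ceil(length/2), length]")
  TRUE
})

#' Construct a motif model
#'
#' @param motif reference motif string, e.g. `"VIPEDV"`.
#' @param minMatches minimum matching positions for a hit; default
#'   `nchar(motif) - 1` (one substitution tolerated).
#' @param name motif name (defaults to the motif string).
#' @param allowed optional list of per-position allowed residue character
#'   vectors; default: each position allows its reference residue only.
#' @return a [MotifModel-class].
#' @examples
#' farRedMotif()       # VIPEDV, 5 of 6
#' whiteLightMotif()   # ENACS, 4 of 5
#' @export
motifModel <- function(motif, minMatches = nchar(motif) - 1L,
                       name = motif, allowed = NULL) {
  motif <- toupper(motif)
  validateSeq(motif, "protein", allowGap = FALSE, what = "motif")
  if (is.null(allowed)) allowed <- as.list(chars(motif))
  m <- new("MotifModel", name = name, motif = motif,
           allowed = lapply(allowed, toupper),
           minMatches = as.integer(minMatches))
  validObject(m)
  m
}

#' @describeIn motifModel the far-red ApcE2 signature (VIPEDV, >= 5/6).
#' @export
farRedMotif <- function() motifModel("VIPEDV", minMatches = 5L)

#' @describeIn motifModel the white-light ApcE1 signature (ENACS, >= 4/5).
#' @export
whiteLightMotif <- function() motifModel("ENACS", minMatches = 4L)

setMethod("show", "MotifModel", function(object) {
  cat(sprintf("MotifModel '%s': %s, >= %d/%d positions\n", object@name,
              object@motif, object@minMatches, nchar(object@motif)))
})

#' Scan a protein for motif hits
#'
#' Slides the motif over the protein and reports every window with at
#' least `minMatches` positions whose residue is in that position's
#' allowed set. `X` (unknown residue) never counts as a match. Hits come
#' in left-to-right order.
#'
#' @param protein a protein string (may contain `X`, `*`).
#' @param motif a [MotifModel-class].
#' @param id record id carried into the output (default `NA`).
#' @param frame reading frame annotation carried into the output.
#' @return data.frame of hits: `id`, `frame`, `position` (1-based protein
#'   coordinate of the window start), `matched` (the window), `matches`,
#'   `score` (= matches / motif length).
#' @examples
#' scanProtein("AAVIPQDVAA", farRedMotif())  # 5/6 hit at position 3
#' @export
scanProtein <- function(protein, motif, id = NA_character_,
                        frame = NA_character_) {
  protein <- toupper(protein)
  len <- nchar(motif@motif)
  n <- nchar(protein)
  empty <- data.frame(id = character(0), frame = character(0),
                      position = integer(0), matched = character(0),
                      matches = integer(0), score = numeric(0))
  if (n < len) return(empty)
  pc <- chars(protein)
  nOff <- n - len + 1L
  counts <- integer(nOff)
  for (j in seq_len(len)) {
    ok <- pc[j:(j + nOff - 1L)] %in% setdiff(motif@allowed[[j]], "X")
    counts <- counts + ok
  }
  pos <- which(counts >= motif@minMatches)
  if (!length(pos)) return(empty)
  data.frame(id = id, frame = frame, position = pos,
             matched = substring(protein, pos, pos + len - 1L),
             matches = counts[pos], score = counts[pos] / len)
}

#' Screen DNA reads or contigs for a protein motif in all six frames
#'
#' Translates each record in all six reading frames and scans every frame
#' with [scanProtein()]. A ~100 bp read can carry a full 6-residue motif
#' (18 coding bases) in one frame; reads where the motif codons are split
#' by the read end produce no hit (no partial-motif calls).
#'
#' @param reads named `DNAStringSet` or named character vector of
#'   ungapped DNA.
#' @param motif a [MotifModel-class].
#' @return data.frame of hits with `id`, `frame` (`+1..-3`), `position`
#'   (protein coordinate within that frame's translation), `matched`,
#'   `matches`, `score`.
#' @export
screenReads <- function(reads, motif) {
  seqs <- toupper(asNamedChar(reads))
  ids <- names(seqs)
  if (is.null(ids)) ids <- as.character(seq_along(seqs))
  # whole-set translation per frame: one Biostrings call per frame, not
  # six per read
  dna <- Biostrings::DNAStringSet(seqs)
  rc <- Biostrings::reverseComplement(dna)
  out <- list()
  for (f in c(1L, 2L, 3L, -1L, -2L, -3L)) {
    strandSet <- if (f > 0) dna else rc
    off <- abs(f) - 1L
    w <- Biostrings::width(strandSet)
    keep <- which(w - off >= 3L)
    if (!length(keep)) next
    n <- w[keep] - off
    n <- n - n %% 3L
    sub <- Biostrings::subseq(strandSet[keep], start = off + 1L, width = n)
    prots <- as.character(Biostrings::translate(sub,
                                                if.fuzzy.codon = "solve"))
    for (k in seq_along(keep)) {
      h <- scanProtein(prots[[k]], motif, id = ids[keep[k]],
                       frame = sprintf("%+d", f))
      if (nrow(h)) {
        h$readIdx <- keep[k]
        out[[length(out) + 1L]] <- h
      }
    }
  }
  if (!length(out)) return(NULL)
  res <- do.call(rbind, out)
  res <- res[order(res$readIdx, res$frame, res$position), , drop = FALSE]
  res$readIdx <- NULL
  rownames(res) <- NULL
  res
}

#' Classify an apcE-like sequence as far-red or white-light
#'
#' Applies the two diagnostic motifs: `FAR_RED` when the far-red motif
#' provides the strongest evidence, `WHITE_LIGHT` when the white-light
#' motif does, `NO_CALL` when neither motif hits. When both motifs hit,
#' the call goes to the motif with the higher best-hit score
#' (matches / motif length): the two motifs occupy homologous positions
#' in real ApcE, so a planted/genuine motif (score 1) outweighs a
#' chance partial match of the other motif elsewhere in a long
#' translation. Equally strong best hits are a genuine conflict and give
#' `AMBIGUOUS`, unless the cysteine diagnostic (below) is checkable, in
#' which case it breaks the tie. DNA input is scanned in all six frames
#' and the call is made on the frame with the best hit.
#'
#' When a reference alignment and the diagnostic cysteine residue index
#' are supplied and the record is present in the alignment, the cysteine
#' rule is applied on top: far-red sequences must lack the
#' phycocyanobilin-binding cysteine at the homologous column,
#' white-light sequences must retain it; a conflict between motif and
#' cysteine evidence yields `AMBIGUOUS`. Motif-only calls are permitted
#' because short fragments often do not cover the cysteine column.
#'
#' @param record one named sequence (character or `XStringSet` element).
#' @param alphabet `"DNA"` (six-frame translated) or `"protein"`.
#' @param frMotif,wlMotif the two [MotifModel-class]s; defaults
#'   [farRedMotif()] and [whiteLightMotif()].
#' @param refAlignment optional named aligned protein set containing the
#'   reference (and, for the cysteine check to apply, the record itself).
#' @param refId reference record id within `refAlignment`.
#' @param cysResidue 1-based ungapped reference index of the diagnostic
#'   cysteine (default 217).
#' @return list: `id`, `label` (one of `FAR_RED`, `WHITE_LIGHT`,
#'   `AMBIGUOUS`, `NO_CALL`), `evidence` (data.frame of best hits per
#'   motif), `cysteine` (`"present"`, `"absent"` or `"unchecked"`),
#'   `frame` (best frame for DNA input, else `NA`).
#' @export
classifyApcE <- function(record, alphabet = c("DNA", "protein"),
                         frMotif = farRedMotif(),
                         wlMotif = whiteLightMotif(),
                         refAlignment = NULL, refId = NULL,
                         cysResidue = 217L) {
  alphabet <- match.arg(alphabet)
  seqs <- toupper(asNamedChar(record))
  id <- names(seqs)
  if (is.null(id)) id <- "query"
  id <- id[1L]; s <- seqs[[1L]]

  bestHit <- function(hits) {
    if (is.null(hits) || !nrow(hits)) return(NULL)
    hits[order(-hits$matches, hits$position), ][1L, , drop = FALSE]
  }
  if (alphabet == "DNA") {
    fr <- bestHit(screenReads(setNames(s, id), frMotif))
    wl <- bestHit(screenReads(setNames(s, id), wlMotif))
  } else {
    fr <- bestHit(scanProtein(s, frMotif, id = id))
    wl <- bestHit(scanProtein(s, wlMotif, id = id))
  }

  cys <- "unchecked"
  if (!is.null(refAlignment) && !is.null(refId)) {
    aln <- asNamedChar(refAlignment)
    if (!refId %in% names(aln))
      fmLookupError(paste0("reference id not in alignment: ", refId))
    if (id %in% names(aln)) {
      col <- mapReferenceToColumn(aln, refId, cysResidue)
      cys <- if (substr(aln[[id]], col, col) == "C") "present" else "absent"
    }
  }

  label <- if (is.null(fr) && is.null(wl)) "NO_CALL"
    else if (is.null(wl)) "FAR_RED"
    else if (is.null(fr)) "WHITE_LIGHT"
    else if (fr$score > wl$score) "FAR_RED"
    else if (wl$score > fr$score) "WHITE_LIGHT"
    else switch(cys, absent = "FAR_RED", present = "WHITE_LIGHT",
                "AMBIGUOUS")
  if (label == "FAR_RED" && cys == "present") label <- "AMBIGUOUS"
  if (label == "WHITE_LIGHT" && cys == "absent") label <- "AMBIGUOUS"

  evidence <- rbind(
    if (!is.null(fr)) cbind(motif = frMotif@name, fr),
    if (!is.null(wl)) cbind(motif = wlMotif@name, wl))
  frame <- if (!is.null(fr)) fr$frame else if (!is.null(wl)) wl$frame
           else NA_character_
  list(id = id, label = label, evidence = evidence, cysteine = cys,
       frame = frame)
}

#' Extract a fixed-length query fragment around a motif hit
#'
#' Cuts a `totalLen`-residue window (default 46, the fragment length used
#' to search unassembled reads) centred on the motif midpoint, shifted
#' inward at the sequence ends so the motif is always fully contained;
#' proteins shorter than `totalLen` are returned whole.
#'
#' @param protein the protein the hit was found in.
#' @param hit one row of [scanProtein()] output.
#' @param totalLen fragment length in residues (default 46).
#' @return the fragment string.
#' @export
extractQueryFragment <- function(protein, hit, totalLen = 46L) {
  protein <- toupper(protein)
  n <- nchar(protein)
  mlen <- nchar(hit$matched[1L])
  if (n <= totalLen) return(protein)
  mid <- hit$position[1L] + (mlen - 1) / 2
  start <- round(mid - (totalLen - 1) / 2)
  start <- max(1L, min(start, n - totalLen + 1L))
  # keep the motif inside after clamping
  start <- min(start, hit$position[1L])
  start <- max(start, hit$position[1L] + mlen - totalLen)
  substr(protein, start, start + totalLen - 1L)
}
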