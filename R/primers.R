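# Degenerate primer design against profiled alignment windows.

#' Wallace-rule melting-temperature range of a degenerate core
#'
#' `Tm = 2(A+T) + 4(G+C)` depends only on the GC count of a concrete
#' oligo, so the bounds over all expansions follow per position: a symbol
#' whose base set lies within \{G,C\} always contributes 4, one that
#' contains no G/C always contributes 2, and a mixed symbol contributes 2
#' or 4. No enumeration is needed.
#'
#' @param core DNA-IUPAC string of length 6-36.
#' @return named numeric vector `c(tmMin=, tmMax=)` in degrees C.
#' @examples
#' tmRange("ACGT")  # 12, 12
#' tmRange("AY")    # would be rejected: too short for a primer core
#' @export
tmRange <- function(core) {
  validateSeq(core, "DNA", allowGap = FALSE, what = "primer core")
  n <- nchar(core)
  if (n < 6L || n > 36L)
    fmValidationError(sprintf(
      "primer core length %d outside supported range 6-36", n))
  .tmRangeUnchecked(core)
}

.tmRangeUnchecked <- function(core) {
  sets <- iupacBases(chars(core))
  gcMin <- vapply(sets, function(s) as.integer(all(s %in% c("G", "C"))), 0L)
  gcMax <- vapply(sets, function(s) as.integer(any(s %in% c("G", "C"))), 0L)
  n <- length(sets)
  c(tmMin = 2 * n + 2 * sum(gcMin), tmMax = 2 * n + 2 * sum(gcMax))
}

#' Degenerate consensus of a profile window
#'
#' At each column the IUPAC symbol covering exactly the set of concrete
#' bases whose frequency is at least `freqFloor`; the consensus base is
#' always included so the set is never empty. Raising the floor excludes
#' rarer bases and so weakly decreases degeneracy ("partially
#' constraining degeneracy"). Ambiguity symbols occurring in the profiled
#' sequences have their frequency split equally over their concrete bases
#' before the floor is applied.
#'
#' @param profile a DNA [ColumnProfile-class].
#' @param start,end 1-based inclusive column window.
#' @param freqFloor frequency threshold in `[0, 1]` (default 0.05:
#'   with 20 profiled sequences every observed base is covered).
#' @param cap maximum tolerated degeneracy; exceeding it is an error
#'   reporting the minimal cap that would succeed.
#' @return the IUPAC core string (length `end - start + 1`).
#' @examples
#' p <- buildProfile(c(a = "ACGTACGTACGT", b = "ACGTACGTACGT",
#'                     c = "ACGTACGTACTT"))
#' consensusDegenerate(p, 1, 12)
#' @export
consensusDegenerate <- function(profile, start, end, freqFloor = 0.05,
                                cap = 512L) {
  if (profile@alphabet != "DNA")
    fmValidationError("primer design requires a DNA profile")
  if (start < 1L || end > profileLength(profile) || start > end)
    fmValidationError("window out of profile bounds")
  if (freqFloor < 0 || freqFloor > 1)
    fmValidationError("'freqFloor' must be in [0, 1]")
  syms <- rownames(profile@freqs)
  core <- vapply(start:end, function(j) {
    f <- profile@freqs[, j]
    base <- setNames(numeric(4), .DNA_LETTERS)
    for (k in seq_along(syms)) {
      if (f[k] <= 0 || syms[k] == "-") next
      bs <- iupacBases(syms[k])[[1L]]
      base[bs] <- base[bs] + f[k] / length(bs)
    }
    keep <- names(base)[base >= freqFloor]
    consBase <- names(base)[which.max(base)]
    keep <- union(keep, consBase)
    iupacSymbolFor(keep)
  }, "")
  core <- collapse0(core)
  deg <- oligoDegeneracy(core)
  if (deg > cap)
    fmValidationError(sprintf(
      "consensus degeneracy %d exceeds cap %d (minimal sufficient cap: %d); raise 'cap' or 'freqFloor'",
      deg, as.integer(cap), deg))
  core
}

#' Attach a concrete 5' tag to a primer
#'
#' Tags (typically 20 bp) are prepended to improve product recovery; they
#' are stored separately from the core so that degeneracy and Tm -- both
#' properties of the template-binding core -- are unchanged.
#'
#' @param primer a [DegeneratePrimer-class].
#' @param tag concrete DNA string (no IUPAC ambiguity), length 0-30.
#' @return the primer with the tag attached.
#' @export
attachTag <- function(primer, tag) {
  tag <- toupper(tag)
  if (nchar(tag) > 30L)
    fmValidationError("tag longer than 30 bases")
  if (grepl("[^ACGT]", tag))
    fmValidationError(sprintf(
      "tag must be concrete DNA (ACGT only), got '%s'", tag))
  degeneratePrimer(primer@core, tag = tag, orientation = primer@orientation)
}

#' Longest exact match between a tag and background sequences
#'
#' Screens a candidate tag for homology seeds in background DNA by exact
#' substring search: the longest common substring between the tag (or its
#' reverse complement) and any background sequence, with every match of
#' at least `minReportLen` listed with its coordinates. A short longest
#' match supports the claim that a tag has low homology to the genomes it
#' will meet.
#'
#' @param tag concrete DNA string.
#' @param background named `DNAStringSet` or character vector (non-empty).
#' @param minReportLen matches at or above this length are listed.
#' @return list with `longest` (integer) and `matches` (data.frame:
#'   `templateId`, `tagStart`, `templateStart`, `length`, `strand`).
#' @export
tagBackgroundCheck <- function(tag, background, minReportLen = 8L) {
  tag <- toupper(tag)
  if (grepl("[^ACGT]", tag))
    fmValidationError("tag must be concrete DNA (ACGT only)")
  bg <- toupper(asNamedChar(background))
  if (!length(bg)) fmValidationError("background must be non-empty")
  ids <- names(bg)
  if (is.null(ids)) ids <- as.character(seq_along(bg))
  hits <- list(); longest <- 0L
  for (strand in c("+", "-")) {
    q <- if (strand == "+") tag else revComp(tag)
    m <- nchar(q)
    for (b in seq_along(bg)) {
      subj <- bg[[b]]
      # scan substring lengths downward from the longest still possible
      for (len in seq.int(min(m, nchar(subj)), 1L)) {
        found <- FALSE
        for (qs in seq_len(m - len + 1L)) {
          piece <- substr(q, qs, qs + len - 1L)
          at <- regexpr(piece, subj, fixed = TRUE)
          if (at > 0) {
            found <- TRUE
            longest <- max(longest, len)
            if (len >= minReportLen) {
              tagStart <- if (strand == "+") qs else m - (qs + len - 1L) + 1L
              hits[[length(hits) + 1L]] <- data.frame(
                templateId = ids[b], tagStart = tagStart,
                templateStart = as.integer(at), length = len,
                strand = strand)
            }
          }
        }
        if (found) break  # longer matches already ruled out for this pair
      }
    }
  }
  matches <- if (length(hits)) unique(do.call(rbind, hits))
  else data.frame(templateId = character(0), tagStart = integer(0),
                  templateStart = integer(0), length = integer(0),
                  strand = character(0))
  rownames(matches) <- NULL
  list(longest = as.integer(longest), matches = matches)
}

# Named degeneracy presets: low constrains the consensus tightly, high
# admits rare bases. Medium is the default (the working compromise
# between coverage of sequence variants and amplification specificity).
#' Degeneracy presets for consensus primer design
#'
#' Three named levels of degeneracy constraint used by [designPair()]:
#' each is a `freqFloor`/`cap` combination. `"medium"` is the default.
#'
#' @param level `"low"`, `"medium"` or `"high"` degeneracy.
#' @return list with `freqFloor` and `cap`.
#' @export
degeneracyPreset <- function(level = c("medium", "low", "high")) {
  level <- match.arg(level)
  switch(level,
         low    = list(freqFloor = 0.25, cap = 64L),
         medium = list(freqFloor = 0.05, cap = 512L),
         high   = list(freqFloor = 0.00, cap = 4096L))
}

#' Design a tagged degenerate primer pair from an island and a universal
#' window
#'
#' The forward core is the degenerate consensus of the target class over
#' the island window (far-red specific); the reverse core is the reverse
#' complement of the degenerate consensus over a window that is conserved
#' in \emph{both} classes (that is what "universal" means), computed on
#' the merged profile. The predicted product on the design template runs
#' from the island start to the universal window end; the design is
#' refused, with the violated constraint named, when that size falls
#' outside `productRange`, when either window fails its conservation
#' requirement, or when the cores' annealing temperatures differ by more
#' than `maxDeltaTm`.
#'
#' @param island one row of [discriminativeIslands()] output (columns
#'   `start`, `end` on the merged alignment).
#' @param targetProfile [ColumnProfile-class] of the target class.
#' @param backgroundProfile [ColumnProfile-class] of the background class.
#' @param universalWindow integer `c(start, end)` columns of the universal
#'   (both-class conserved) reverse-primer window.
#' @param template the named design template record (aligned sequence, a
#'   member of the merged alignment) as a one-element named character or
#'   `DNAStringSet`; product size is measured on its ungapped coordinates.
#' @param productRange numeric `c(min, max)` acceptable product size, bp.
#' @param maxDeltaTm maximum annealing-temperature mismatch, degrees C.
#' @param minUniversalConservation per-column conservation both classes
#'   must reach inside the universal window (default 0.8).
#' @param freqFloor,cap consensus constraints, see [consensusDegenerate()]
#'   and [degeneracyPreset()].
#' @param fwTag,rvTag optional concrete 5' tags (e.g. 20 bp) attached to
#'   the cores.
#' @return a [PrimerPair-class].
#' @export
designPair <- function(island, targetProfile, backgroundProfile,
                       universalWindow, template,
                       productRange = c(1000, 1400), maxDeltaTm = 6,
                       minUniversalConservation = 0.8,
                       freqFloor = 0.05, cap = 512L,
                       fwTag = "", rvTag = "") {
  uw <- as.integer(universalWindow)
  if (length(uw) != 2L || uw[1L] > uw[2L])
    fmValidationError("'universalWindow' must be c(start, end), start <= end")
  uidx <- uw[1L]:uw[2L]
  badT <- conservation(targetProfile)[uidx] < minUniversalConservation
  badB <- conservation(backgroundProfile)[uidx] < minUniversalConservation
  if (any(badT) || any(badB))
    fmDesignError(sprintf(
      "universal window %d-%d is not conserved in both classes (%d target, %d background columns below %.2f)",
      uw[1L], uw[2L], sum(badT), sum(badB), minUniversalConservation))

  # merged profile for the universal consensus: average the class
  # frequency matrices weighted by class size
  merged <- .mergeProfiles(targetProfile, backgroundProfile)
  fwCore <- consensusDegenerate(targetProfile, island$start, island$end,
                                freqFloor = freqFloor, cap = cap)
  rvCore <- revComp(consensusDegenerate(merged, uw[1L], uw[2L],
                                        freqFloor = freqFloor, cap = cap))

  # product size on the ungapped template
  tmpl <- asNamedChar(template)
  tid <- names(tmpl)
  if (is.null(tid)) fmValidationError("'template' must be named")
  mp <- mapColumnToReference(tmpl, tid[1L], c(island$start, uw[2L]))
  product <- mp$residue[2L] - mp$residue[1L] + 1L
  if (product < productRange[1L] || product > productRange[2L])
    fmDesignError(sprintf(
      "predicted product %d bp outside requested range %d-%d bp",
      product, as.integer(productRange[1L]), as.integer(productRange[2L])))

  fw <- degeneratePrimer(fwCore, orientation = "forward")
  rv <- degeneratePrimer(rvCore, orientation = "reverse")
  if (nzchar(fwTag)) fw <- attachTag(fw, fwTag)
  if (nzchar(rvTag)) rv <- attachTag(rv, rvTag)
  pp <- primerPair(fw, rv, productMin = product, productMax = product)
  if (pp@deltaTm > maxDeltaTm)
    fmDesignError(sprintf(
      "annealing mismatch deltaTm = %.1f C exceeds maximum %.1f C",
      pp@deltaTm, maxDeltaTm))
  pp
}

.mergeProfiles <- function(a, b) {
  if (profileLength(a) != profileLength(b))
    fmValidationError("profiles differ in length")
  syms <- sort(union(rownames(a@freqs), rownames(b@freqs)))
  pad <- function(p) {
    m <- matrix(0, length(syms), profileLength(p),
                dimnames = list(syms, NULL))
    m[rownames(p@freqs), ] <- p@freqs
    m
  }
  wa <- a@nseq * (1 - a@gapFraction)
  wb <- b@nseq * (1 - b@gapFraction)
  tot <- pmax(wa + wb, 1e-12)
  freqs <- sweep(pad(a), 2L, wa, "*") + sweep(pad(b), 2L, wb, "*")
  freqs <- sweep(freqs, 2L, tot, "/")
  gapFrac <- (a@nseq * a@gapFraction + b@nseq * b@gapFraction) /
    (a@nseq + b@nseq)
  consIdx <- apply(freqs, 2L, which.max)
  nonEmpty <- colSums(freqs) > 0
  cons <- ifelse(nonEmpty, syms[consIdx], "-")
  consv <- ifelse(nonEmpty, freqs[cbind(consIdx, seq_len(ncol(freqs)))], 0)
  new("ColumnProfile", freqs = freqs, gapFraction = as.numeric(gapFrac),
      consensus = cons, conservation = as.numeric(consv),
      nseq = a@nseq + b@nseq, alphabet = a@alphabet)
}

#' Write primers as a TSV manifest
#'
#' @param pairs a list of [PrimerPair-class] objects (or a single pair).
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writePrimerTsv <- function(pairs, path) {
  if (is(pairs, "PrimerPair")) pairs <- list(pairs)
  rows <- lapply(seq_along(pairs), function(i) {
    pp <- pairs[[i]]
    one <- function(p, role) data.frame(
      id = sprintf("pair%d_%s", i, substr(role, 1, 2)),
      orientation = role, tag = primerTag(p), core = primerCore(p),
      sequence = primerSequence(p), degeneracy = primerDegeneracy(p),
      tmMin = p@tmMin, tmMax = p@tmMax,
      productMin = pp@productMin, productMax = pp@productMax,
      deltaTm = pp@deltaTm)
    rbind(one(pairForward(pp), "forward"), one(pairReverse(pp), "reverse"))
  })
  writeTsv(do.call(rbind, rows), path)
}
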