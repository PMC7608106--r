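# Distance-based phylogenetic placement of recovered fragments.

#' p-distance between two aligned sequences
#'
#' Proportion of differing positions among comparable columns: columns
#' where either sequence has a gap or an ambiguity symbol (anything
#' outside A/C/G/T for DNA, or `X`/`*` for protein) are excluded.
#'
#' @param a,b equal-length aligned sequence strings.
#' @param minOverlap minimum number of comparable columns; fewer is an
#'   insufficient-overlap error, never `NaN`.
#' @param alphabet `"DNA"` or `"protein"`.
#' @return the p-distance in `[0, 1]`.
#' @examples
#' pDistance("ACGT", "ACGA", minOverlap = 4)  # 0.25
#' @export
pDistance <- function(a, b, minOverlap = 100L,
                      alphabet = c("DNA", "protein")) {
  alphabet <- match.arg(alphabet)
  a <- toupper(as.character(a)[[1L]]); b <- toupper(as.character(b)[[1L]])
  if (nchar(a) != nchar(b))
    fmValidationError("aligned sequences must have equal length")
  ca <- chars(a); cb <- chars(b)
  unamb <- if (alphabet == "DNA") .DNA_LETTERS
           else setdiff(.ALPHABETS$protein, c("X", "*"))
  comp <- ca %in% unamb & cb %in% unamb
  if (sum(comp) < minOverlap)
    fmOverlapError(sprintf(
      "only %d comparable columns; %d required", sum(comp),
      as.integer(minOverlap)))
  sum(ca[comp] != cb[comp]) / sum(comp)
}

#' Pairwise p-distance matrix of an aligned set
#'
#' @param alignment named aligned `XStringSet` or character vector.
#' @inheritParams pDistance
#' @param columns optional integer vector restricting all comparisons to
#'   a column subset (used by [placeFragment()] so every pair is measured
#'   on the same fragment-covered region).
#' @return symmetric numeric matrix with zero diagonal, labelled by ids.
#' @export
distanceMatrix <- function(alignment, minOverlap = 100L,
                           alphabet = c("DNA", "protein"),
                           columns = NULL) {
  alphabet <- match.arg(alphabet)
  seqs <- toupper(asNamedChar(alignment))
  ids <- names(seqs)
  if (is.null(ids)) fmValidationError("alignment records must be named")
  if (!is.null(columns))
    seqs <- vapply(seqs, function(s)
      collapse0(chars(s)[columns]), "")
  n <- length(seqs)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
    d[i, j] <- d[j, i] <- pDistance(seqs[[i]], seqs[[j]],
                                    minOverlap = minOverlap,
                                    alphabet = alphabet)
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Classic Saitou-Nei agglomeration (exact on additive matrices),
#' delegated to `ape::nj()`; negative branch lengths -- which NJ can
#' produce on non-additive input -- are clamped to zero, with the total
#' clamped deficit recorded in the tree's `negativeDeficit` attribute.
#'
#' @param dm symmetric distance matrix with labels (>= 3 taxa).
#' @return an `ape::phylo` unrooted tree with branch lengths.
#' @export
njTree <- function(dm) {
  dm <- as.matrix(dm)
  if (nrow(dm) < 3L)
    fmValidationError("neighbor-joining needs at least 3 taxa")
  if (any(!is.finite(dm)))
    fmValidationError("distance matrix has non-finite entries")
  if (max(abs(dm - t(dm))) > 1e-12 || any(diag(dm) != 0))
    fmValidationError("distance matrix must be symmetric with zero diagonal")
  tree <- ape::nj(as.dist(dm))
  deficit <- -sum(tree$edge.length[tree$edge.length < 0])
  tree$edge.length[tree$edge.length < 0] <- 0
  attr(tree, "negativeDeficit") <- deficit
  tree
}

#' PlacementResult: where a fragment falls among references
#'
#' @slot fragmentId the placed fragment's id.
#' @slot ranking data.frame of references sorted by ascending p-distance.
#' @slot tree `ape::phylo` NJ tree over references + fragment.
#' @slot sister character vector: reference taxa of the fragment's sister
#'   group on the (rooted) tree.
#' @slot columns integer vector of reference-alignment columns covered by
#'   the fragment (the region all distances were computed on).
#' @exportClass PlacementResult
setClass("PlacementResult",
  representation(fragmentId = "character", ranking = "data.frame",
                 tree = "ANY", sister = "character", columns = "integer"))

setValidity("PlacementResult", function(object) {
  r <- object@ranking
  if (!all(c("referenceId", "distance") %in% names(r)))
    return("ranking must have columns referenceId, distance")
  if (is.unsorted(r$distance)) return("ranking must be sorted ascending")
  TRUE
})

setMethod("show", "PlacementResult", function(object) {
  cat(sprintf("PlacementResult for '%s' (%d reference taxa, %d columns)\n",
              object@fragmentId, nrow(object@ranking),
              length(object@columns)))
  cat(sprintf("  nearest: %s (p = %.4f)\n  sister group: %s\n",
              object@ranking$referenceId[1L], object@ranking$distance[1L],
              paste(object@sister, collapse = ", ")))
})

#' @describeIn placeFragment ranked reference distances of a result.
#' @param x a `PlacementResult`.
#' @export
placementRanking <- function(x) x@ranking

#' @describeIn placeFragment the fragment's sister group (reference ids).
#' @export
placementSister <- function(x) x@sister

#' @describeIn placeFragment the NJ tree (`ape::phylo`).
#' @export
placementTree <- function(x) x@tree

#' @describeIn placeFragment serialise the NJ tree as newick.
#' @param path output path.
#' @export
writePlacementNewick <- function(x, path) {
  ape::write.tree(placementTree(x), file = path)
  invisible(path)
}

#' Place a fragment among reference sequences by distance and NJ
#'
#' Aligns the fragment semi-globally (fragment global, reference local;
#' +1 match, -1 mismatch, -2 per gap position) against each reference's
#' ungapped sequence -- both strands for DNA, keeping the better score --
#' maps it into reference-alignment columns via the best-scoring
#' reference, computes p-distances over the fragment-covered columns
#' only, and reports the nearest references plus a neighbor-joining tree
#' of references + fragment with the fragment's sister group. Rooting:
#' at `outgroup` when given, else at the reference farthest from the
#' fragment (an implicit outgroup making "sister group" well defined on
#' an otherwise unrooted NJ tree).
#'
#' @param fragment one named ungapped sequence (character or
#'   `XStringSet`).
#' @param refAlignment named aligned reference set (same alphabet).
#' @param minOverlap minimum comparable columns (default 100).
#' @param alphabet `"DNA"` or `"protein"`.
#' @param outgroup optional reference id to root the NJ tree at.
#' @return a [PlacementResult-class].
#' @export
placeFragment <- function(fragment, refAlignment, minOverlap = 100L,
                          alphabet = c("DNA", "protein"),
                          outgroup = NULL) {
  alphabet <- match.arg(alphabet)
  frag <- toupper(asNamedChar(fragment))
  fid <- names(frag)
  if (is.null(fid)) fid <- "fragment"
  fid <- fid[1L]; frag <- frag[[1L]]
  refs <- toupper(asNamedChar(refAlignment))
  if (is.null(names(refs)))
    fmValidationError("reference alignment records must be named")
  if (fid %in% names(refs))
    fmValidationError("fragment id collides with a reference id")
  if (nchar(frag) < minOverlap)
    fmOverlapError(sprintf(
      "fragment length %d below minimum overlap %d", nchar(frag),
      as.integer(minOverlap)))

  sub <- .unitSubstitutionMatrix(alphabet)
  best <- NULL
  for (rid in names(refs)) {
    ungapped <- gsub("-", "", refs[[rid]], fixed = TRUE)
    cands <- frag
    if (alphabet == "DNA") cands <- c(cands, revComp(frag))
    for (q in cands) {
      al <- Biostrings::pairwiseAlignment(
        q, ungapped, type = "global-local", substitutionMatrix = sub,
        gapOpening = 0, gapExtension = 2)
      if (is.null(best) || Biostrings::score(al) > best$score)
        best <- list(score = Biostrings::score(al), al = al, rid = rid,
                     query = q)
    }
  }

  # build the fragment's row in reference-alignment coordinates
  refChars <- chars(refs[[best$rid]])
  ungappedToCol <- which(refChars != "-")
  alignedQ <- chars(as.character(Biostrings::alignedPattern(best$al)))
  alignedS <- chars(as.character(Biostrings::alignedSubject(best$al)))
  sPos <- Biostrings::start(Biostrings::subject(best$al)) - 1L
  row <- rep("-", length(refChars))
  for (k in seq_along(alignedS)) {
    if (alignedS[k] != "-") {
      sPos <- sPos + 1L
      if (alignedQ[k] != "-") row[ungappedToCol[sPos]] <- alignedQ[k]
    }
    # fragment residues inserted relative to the reference have no
    # column of their own and are dropped (reference coordinates rule)
  }
  columns <- which(row != "-")
  if (length(columns) < minOverlap)
    fmOverlapError(sprintf(
      "fragment covers %d reference columns; %d required",
      length(columns), as.integer(minOverlap)))

  aln <- c(refs, setNames(collapse0(row), fid))
  dm <- distanceMatrix(aln, minOverlap = min(minOverlap, length(columns)),
                       alphabet = alphabet, columns = columns)
  ranking <- data.frame(referenceId = names(refs),
                        distance = dm[fid, names(refs)])
  ranking <- ranking[order(ranking$distance, ranking$referenceId), ]
  rownames(ranking) <- NULL

  tree <- njTree(dm)
  rootAt <- if (!is.null(outgroup)) {
    if (!outgroup %in% names(refs))
      fmLookupError(paste0("outgroup not among references: ", outgroup))
    outgroup
  } else ranking$referenceId[nrow(ranking)]
  rooted <- ape::root(tree, outgroup = rootAt, resolve.root = TRUE)
  sister <- .sisterGroup(rooted, fid)

  new("PlacementResult", fragmentId = fid, ranking = ranking,
      tree = tree, sister = sister, columns = as.integer(columns))
}

.unitSubstitutionMatrix <- function(alphabet) {
  letters <- if (alphabet == "DNA") c(.DNA_LETTERS, "N")
             else .ALPHABETS$protein
  m <- matrix(-1, length(letters), length(letters),
              dimnames = list(letters, letters))
  diag(m) <- 1
  m
}

# tips descending from the sibling of `tip`'s parent edge on a rooted tree
.sisterGroup <- function(tree, tip) {
  tipIdx <- match(tip, tree$tip.label)
  parent <- tree$edge[tree$edge[, 2L] == tipIdx, 1L]
  kids <- tree$edge[tree$edge[, 1L] == parent, 2L]
  kids <- setdiff(kids, tipIdx)
  tips <- unlist(lapply(kids, function(k) .descendantTips(tree, k)))
  setdiff(tree$tip.label[tips], tip)
}

.descendantTips <- function(tree, node) {
  nTips <- length(tree$tip.label)
  if (node <= nTips) return(node)
  out <- integer(0)
  stack <- node
  while (length(stack)) {
    cur <- stack[1L]; stack <- stack[-1L]
    kids <- tree$edge[tree$edge[, 1L] == cur, 2L]
    out <- c(out, kids[kids <= nTips])
    stack <- c(stack, kids[kids > nTips])
  }
  out
}
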