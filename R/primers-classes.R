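# S4 classes for tagged degenerate primers and primer pairs.

#' DegeneratePrimer: an IUPAC oligo core with an optional 5' tag
#'
#' A degenerate primer is a variable 3' core written in IUPAC ambiguity
#' codes plus an optional non-variable 5' tag of concrete bases (tags
#' improve product recovery and carry no template specificity, so
#' degeneracy and melting temperature are computed on the core only).
#' The Tm range uses the Wallace rule, `2(A+T) + 4(G+C)`, over the
#' concrete oligos the core expands to.
#'
#' @slot core DNA-IUPAC string (the 3' template-binding section).
#' @slot tag concrete DNA string, possibly empty.
#' @slot orientation `"forward"` or `"reverse"`.
#' @slot degeneracy product of per-core-position IUPAC set sizes.
#' @slot tmMin,tmMax Wallace-rule Tm bounds (degrees C) over the core's
#'   expansions.
#' @exportClass DegeneratePrimer
setClass("DegeneratePrimer",
  representation(core = "character", tag = "character",
                 orientation = "character", degeneracy = "numeric",
                 tmMin = "numeric", tmMax = "numeric"))

setValidity("DegeneratePrimer", function(object) {
  if (!object@orientation %in% c("forward", "reverse"))
    return("orientation must be 'forward' or 'reverse'")
  if (nzchar(object@tag) && grepl("[^ACGT]", object@tag))
    return("tag must contain concrete bases (ACGT) only")
  if (object@degeneracy != oligoDegeneracy(object@core))
    return("degeneracy inconsistent with core")
  if (object@tmMin > object@tmMax) return("tmMin > tmMax")
  TRUE
})

#' Construct a degenerate primer
#'
#' @param core DNA-IUPAC core (no gaps), length 6-36.
#' @param tag concrete 5' tag (default none); see [attachTag()].
#' @param orientation `"forward"` or `"reverse"`.
#' @return a [DegeneratePrimer-class] object.
#' @examples
#' degeneratePrimer("GTNATHCCNGARGAYGT")
#' @export
degeneratePrimer <- function(core, tag = "", orientation = "forward") {
  validateSeq(core, "DNA", allowGap = FALSE, what = "primer core")
  tm <- tmRange(core)
  p <- new("DegeneratePrimer", core = core, tag = toupper(tag),
           orientation = orientation,
           degeneracy = oligoDegeneracy(core),
           tmMin = tm[["tmMin"]], tmMax = tm[["tmMax"]])
  validObject(p)
  p
}

#' @describeIn degeneratePrimer the IUPAC core string.
#' @param x a `DegeneratePrimer`.
#' @export
primerCore <- function(x) x@core

#' @describeIn degeneratePrimer the 5' tag (may be `""`).
#' @export
primerTag <- function(x) x@tag

#' @describeIn degeneratePrimer full 5'->3' sequence, tag + core.
#' @export
primerSequence <- function(x) paste0(x@tag, x@core)

#' @describeIn degeneratePrimer number of concrete oligos represented.
#' @export
primerDegeneracy <- function(x) x@degeneracy

#' @describeIn degeneratePrimer Wallace-rule Tm bounds of the core.
#' @export
primerTm <- function(x) c(tmMin = x@tmMin, tmMax = x@tmMax)

setMethod("show", "DegeneratePrimer", function(object) {
  cat(sprintf("DegeneratePrimer (%s): 5'-%s%s-3'\n", object@orientation,
              if (nzchar(object@tag)) paste0("[", object@tag, "]") else "",
              object@core))
  cat(sprintf("  degeneracy %d, core Tm %.0f-%.0f C\n",
              object@degeneracy, object@tmMin, object@tmMax))
})

#' PrimerPair: a forward/reverse primer pair with product expectations
#'
#' @slot forward,reverse [DegeneratePrimer-class] objects.
#' @slot productMin,productMax expected product size bounds (bp) on the
#'   design template.
#' @slot deltaTm absolute difference of the two cores' Tm-range midpoints
#'   (degrees C).
#' @exportClass PrimerPair
setClass("PrimerPair",
  representation(forward = "DegeneratePrimer", reverse = "DegeneratePrimer",
                 productMin = "numeric", productMax = "numeric",
                 deltaTm = "numeric"))

setValidity("PrimerPair", function(object) {
  if (object@forward@orientation != "forward" ||
      object@reverse@orientation != "reverse")
    return("pair must hold one forward and one reverse primer")
  if (object@productMin > object@productMax)
    return("productMin > productMax")
  if (object@deltaTm < 0) return("deltaTm must be non-negative")
  TRUE
})

#' Construct a primer pair
#'
#' @param forward,reverse [DegeneratePrimer-class] objects with matching
#'   orientations.
#' @param productMin,productMax expected amplicon size bounds in bp.
#' @return a [PrimerPair-class]; `deltaTm` is computed from the cores.
#' @export
primerPair <- function(forward, reverse, productMin, productMax) {
  mid <- function(p) (p@tmMin + p@tmMax) / 2
  pp <- new("PrimerPair", forward = forward, reverse = reverse,
            productMin = as.numeric(productMin),
            productMax = as.numeric(productMax),
            deltaTm = abs(mid(forward) - mid(reverse)))
  validObject(pp)
  pp
}

#' @describeIn primerPair forward primer.
#' @param x a `PrimerPair`.
#' @export
pairForward <- function(x) x@forward

#' @describeIn primerPair reverse primer.
#' @export
pairReverse <- function(x) x@reverse

#' @describeIn primerPair annealing-temperature mismatch (degrees C).
#' @export
pairDeltaTm <- function(x) x@deltaTm

#' @describeIn primerPair expected product size bounds (bp).
#' @export
pairProductRange <- function(x) c(min = x@productMin, max = x@productMax)

setMethod("show", "PrimerPair", function(object) {
  cat("PrimerPair\n  fw: "); show(object@forward)
  cat("  rv: "); show(object@reverse)
  cat(sprintf("  product %d-%d bp, deltaTm %.1f C\n",
              as.integer(object@productMin), as.integer(object@productMax),
              object@deltaTm))
})
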