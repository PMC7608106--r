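# Synthetic two-class apcE-like gene families.
#
# The generator emulates the structure the marker method assumes: a
# ~2270 bp gene in two paralog classes descending from one ancestor,
# with the far-red class carrying the VIPEDV motif codons at residues
# 204-209 and no cysteine at residue 217, the white-light class carrying
# ENACS codons at the homologous residues 204-208 plus the diagnostic
# cysteine, and a block conserved in both classes where the universal
# reverse primer sits, 1,200 bp downstream of the island start so the
# designed pair yields the ~1.2 kb amplicon geometry.

.SENSE_CODONS <- local({
  b <- c("A", "C", "G", "T")
  all <- as.vector(outer(as.vector(outer(b, b, paste0)), b, paste0))
  setdiff(all, c("TAA", "TAG", "TGA"))
})

# fixed codon spellings of the planted motifs (planted columns are never
# mutated, so one spelling per class suffices)
.FR_MOTIF_NT <- "GTTATCCCAGAAGATGTG"  # VIPEDV, residues 204-209
.WL_MOTIF_NT <- "GAAAACGCTTGCAGC"     # ENACS,  residues 204-208
.CYS_CODON   <- "TGC"                 # background residue 217
.NOCYS_CODON <- "AGC"                 # target residue 217 (serine)
# universal (both-class conserved) reverse-primer block: sense codons,
# GC chosen so its Wallace Tm (52 C) matches the forward island core --
# the annealing-temperature matching the design step assumes
.UNIVERSAL_NT <- "GAAGCTGGTCGTATTACA"

#' Specification of a synthetic two-class apcE-like family
#'
#' Defaults are the study conditions the rest of the package is exercised
#' under: 20 target (far-red) + 20 background (white-light) sequences,
#' 2,270 bp genes, per-site substitution probability 0.05 outside planted
#' columns, no indels. The forward island (VIPEDV codons) occupies
#' nucleotides 610-627 (residues 204-209); the diagnostic cysteine codon,
#' 649-651 (residue 217, background only); the universal reverse-primer
#' block is 18 bp ending 1,200 bp after the island start (columns
#' 1792-1809 on the default gene), conserved in both classes.
#'
#' @param nTarget,nBackground class sizes (positive).
#' @param geneLengthBp gene length in bp (>= 690 so residue 217 exists).
#' @param subRate per-site substitution probability outside planted
#'   columns, in `[0, 1]`.
#' @param classDivergence per-site divergence between the two class
#'   ancestors outside planted columns (default 0.15): apcE1 and apcE2
#'   are anciently diverged paralog clades, not one pool of sequences
#'   differing only at the motif, and without this divergence no
#'   placement method could separate the classes.
#' @param indelRate per-sequence probability of one codon-length deletion
#'   (rendered as gap columns so the merged alignment stays consistent);
#'   default 0.
#' @param seed integer; fully determines the family.
#' @return a `FamilySpec` list (class `"FamilySpec"`).
#' @export
familySpec <- function(nTarget = 20L, nBackground = 20L,
                       geneLengthBp = 2270L, subRate = 0.05,
                       classDivergence = 0.15,
                       indelRate = 0, seed = 1L) {
  if (nTarget < 1L || nBackground < 1L)
    fmValidationError("class sizes must be positive")
  if (geneLengthBp < 690L)
    fmValidationError(
      "geneLengthBp must be >= 690 so that residue 217 exists")
  if (subRate < 0 || subRate > 1)
    fmValidationError("'subRate' must be in [0, 1]")
  if (classDivergence < 0 || classDivergence > 1)
    fmValidationError("'classDivergence' must be in [0, 1]")
  islandStart <- (204L - 1L) * 3L + 1L          # 610
  islandEnd <- 209L * 3L                        # 627
  uEnd <- islandStart + 1200L - 1L              # 1809: ~1.2 kb product
  if (uEnd > geneLengthBp) uEnd <- geneLengthBp # short test genes
  uStart <- uEnd - 18L + 1L
  structure(list(
    nTarget = as.integer(nTarget), nBackground = as.integer(nBackground),
    geneLengthBp = as.integer(geneLengthBp), subRate = subRate,
    classDivergence = classDivergence,
    indelRate = indelRate, seed = as.integer(seed),
    islandStart = islandStart, islandEnd = islandEnd,
    wlEnd = islandStart + nchar(.WL_MOTIF_NT) - 1L,
    cysStart = (217L - 1L) * 3L + 1L, cysEnd = 217L * 3L,
    universalStart = uStart, universalEnd = uEnd),
    class = "FamilySpec")
}

.mutate <- function(cc, mutable, rate) {
  if (rate <= 0) return(cc)
  hit <- which(mutable & runif(length(cc)) < rate)
  if (length(hit)) {
    cc[hit] <- vapply(cc[hit], function(b)
      sample(setdiff(.DNA_LETTERS, b), 1L), "")
  }
  cc
}

#' Generate a synthetic two-class gene family
#'
#' Draws a random ancestral gene of sense codons, derives a target-class
#' ancestor (VIPEDV codons planted at residues 204-209, serine at 217)
#' and a background-class ancestor (ENACS codons at 204-208, cysteine at
#' 217), then mutates each descendant independently at `subRate` per
#' site outside the planted columns; the universal reverse-primer block
#' is immutable in both classes. Gap-free by default, so the merged
#' alignment coordinate system equals the ancestral gene's; codon-length
#' deletions (when `indelRate > 0`) become gap columns in that same
#' system. Byte-identical output under the same seed.
#'
#' @param spec a [familySpec()].
#' @return list with `alignment` (merged aligned `DNAStringSet`, targets
#'   first), `ungapped` (gap-free `DNAStringSet`), `classMap`
#'   (data.frame `id`, `class`), `truth` (planted coordinates on the
#'   alignment system plus per-record ungapped island starts), and
#'   `spec`.
#' @export
generateFamily <- function(spec) {
  stopifnot(inherits(spec, "FamilySpec"))
  L <- spec$geneLengthBp
  withSeed(spec$seed, {
    nCodon <- L %/% 3L
    anc <- chars(paste0(
      collapse0(sample(.SENSE_CODONS, nCodon, replace = TRUE)),
      collapse0(sample(.DNA_LETTERS, L %% 3L, replace = TRUE))))
    plant <- function(cc, nt, at) {
      cc[at:(at + nchar(nt) - 1L)] <- chars(nt); cc
    }
    anc <- plant(anc, .UNIVERSAL_NT, spec$universalStart)
    uCols <- spec$universalStart:spec$universalEnd
    tImmutable <- c(spec$islandStart:spec$islandEnd,
                    spec$cysStart:spec$cysEnd, uCols)
    bImmutable <- c(spec$islandStart:spec$wlEnd,
                    spec$cysStart:spec$cysEnd, uCols)
    tAnc <- plant(plant(anc, .FR_MOTIF_NT, spec$islandStart),
                  .NOCYS_CODON, spec$cysStart)
    # paralog divergence: the background class ancestor drifts away from
    # the common ancestor before its own motifs are planted
    bAnc <- .mutate(anc, !(seq_len(L) %in% bImmutable),
                    spec$classDivergence)
    bAnc <- plant(plant(bAnc, .WL_MOTIF_NT, spec$islandStart),
                  .CYS_CODON, spec$cysStart)
    descend <- function(ancCC, immutable, n, prefix) {
      mutable <- !(seq_len(L) %in% immutable)
      vapply(seq_len(n), function(i) {
        cc <- .mutate(ancCC, mutable, spec$subRate)
        if (spec$indelRate > 0 && runif(1L) < spec$indelRate) {
          delCodons <- setdiff(seq_len(nCodon), unique(
            (immutable - 1L) %/% 3L + 1L))
          k <- sample(delCodons, 1L)
          cc[((k - 1L) * 3L + 1L):(k * 3L)] <- "-"
        }
        collapse0(cc)
      }, "")
    }
    tSeqs <- descend(tAnc, tImmutable, spec$nTarget, "target")
    bSeqs <- descend(bAnc, bImmutable, spec$nBackground, "background")
    ids <- c(sprintf("target_%02d", seq_len(spec$nTarget)),
             sprintf("background_%02d", seq_len(spec$nBackground)))
    aligned <- setNames(c(tSeqs, bSeqs), ids)
    ungapped <- setNames(gsub("-", "", aligned, fixed = TRUE), ids)
    classMap <- data.frame(
      id = ids,
      class = rep(c("target", "background"),
                  c(spec$nTarget, spec$nBackground)))
    perRecord <- data.frame(
      id = ids,
      islandStartUngapped = vapply(aligned, function(s)
        sum(chars(substr(s, 1L, spec$islandStart)) != "-"), 0L),
      row.names = NULL)
    list(alignment = Biostrings::DNAStringSet(aligned),
         ungapped = Biostrings::DNAStringSet(ungapped),
         classMap = classMap,
         truth = list(
           islandStart = spec$islandStart, islandEnd = spec$islandEnd,
           wlEnd = spec$wlEnd, cysStart = spec$cysStart,
           cysEnd = spec$cysEnd, universalStart = spec$universalStart,
           universalEnd = spec$universalEnd,
           frMotif = "VIPEDV", wlMotif = "ENACS",
           motifResidues = 204L:209L, cysResidue = 217L,
           ampliconLength = spec$universalEnd - spec$islandStart + 1L,
           perRecord = perRecord),
         spec = spec)
  })
}

#' Sample error-bearing short reads from a family
#'
#' Reads are drawn uniformly from both strands of the ungapped family
#' sequences at the requested coverage, with independent per-base
#' substitution errors. Provenance (source record, 1-based start on the
#' plus strand, strand) is encoded in the read ids as
#' `read_<k>|src=...|start=...|strand=...`.
#'
#' @param family output of [generateFamily()].
#' @param readLengthBp read length (default 100, the short-read regime
#'   the motif screen is designed for).
#' @param coverage mean per-base coverage per gene (positive).
#' @param errorRate per-base substitution error probability.
#' @param seed integer seed (independent of the family seed).
#' @return a named `DNAStringSet` of reads.
#' @export
generateReads <- function(family, readLengthBp = 100L, coverage = 30,
                          errorRate = 0, seed = 1L) {
  if (coverage <= 0) fmValidationError("'coverage' must be positive")
  if (errorRate < 0 || errorRate > 1)
    fmValidationError("'errorRate' must be in [0, 1]")
  seqs <- as.character(family$ungapped)
  if (readLengthBp > min(nchar(seqs)))
    fmValidationError("read length exceeds the shortest gene")
  withSeed(seed, {
    perGene <- lapply(names(seqs), function(g) {
      s <- seqs[[g]]; L <- nchar(s)
      n <- ceiling(coverage * L / readLengthBp)
      starts <- sample.int(L - readLengthBp + 1L, n, replace = TRUE)
      strands <- sample(c("+", "-"), n, replace = TRUE)
      reads <- substring(s, starts, starts + readLengthBp - 1L)
      minus <- strands == "-"
      if (any(minus))
        reads[minus] <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAStringSet(reads[minus])))
      if (errorRate > 0) {
        bases <- matrix(unlist(strsplit(reads, "", fixed = TRUE),
                               use.names = FALSE), nrow = readLengthBp)
        hit <- which(runif(length(bases)) < errorRate)
        if (length(hit))
          bases[hit] <- vapply(bases[hit], function(b)
            sample(setdiff(.DNA_LETTERS, b), 1L), "", USE.NAMES = FALSE)
        reads <- apply(bases, 2L, collapse0)
      }
      list(reads = reads,
           ids = sprintf("|src=%s|start=%d|strand=%s", g, starts, strands))
    })
    reads <- unlist(lapply(perGene, `[[`, "reads"), use.names = FALSE)
    suffix <- unlist(lapply(perGene, `[[`, "ids"), use.names = FALSE)
    setNames(Biostrings::DNAStringSet(reads),
             sprintf("read_%05d%s", seq_along(reads), suffix))
  })
}
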