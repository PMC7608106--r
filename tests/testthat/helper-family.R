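# Shared fixture builders (all generated in code, fully seeded).

smallFamily <- function(seed = 1, nTarget = 6, nBackground = 6,
                        geneLengthBp = 2270, subRate = 0.05, ...) {
  generateFamily(familySpec(nTarget = nTarget, nBackground = nBackground,
                            geneLengthBp = geneLengthBp, subRate = subRate,
                            seed = seed, ...))
}

familyClassSeqs <- function(fam) {
  aln <- as.character(fam$alignment)
  list(target = aln[fam$classMap$class == "target"],
       background = aln[fam$classMap$class == "background"])
}

familyProfiles <- function(fam) {
  cls <- familyClassSeqs(fam)
  list(target = buildProfile(cls$target),
       background = buildProfile(cls$background))
}

# design the pair the default pipeline produces for a family
familyPair <- function(fam, ...) {
  pr <- familyProfiles(fam)
  isl <- discriminativeIslands(pr$target, pr$background)
  designPair(isl[1, ], pr$target, pr$background,
             universalWindow = c(fam$truth$universalStart,
                                 fam$truth$universalEnd),
             template = familyClassSeqs(fam)$target[1], ...)
}

# frame +1 protein alignment of the family (deleted codons become '-')
familyProteins <- function(fam) {
  aln <- as.character(fam$alignment)
  gapless <- !grepl("-", aln, fixed = TRUE)
  out <- setNames(character(length(aln)), names(aln))
  if (any(gapless)) out[gapless] <- translateSet(aln[gapless], 1)
  for (id in names(aln)[!gapless]) {
    s <- aln[[id]]
    cod <- substring(s, seq(1, nchar(s) - 2, 3), seq(3, nchar(s), 3))
    gapIdx <- grepl("-", cod, fixed = TRUE)
    prot <- strsplit(translateSet(paste(cod[!gapIdx], collapse = ""), 1),
                     "")[[1]]
    full <- character(length(cod))
    full[gapIdx] <- "-"
    full[!gapIdx] <- prot
    out[id] <- paste(full, collapse = "")
  }
  out
}
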