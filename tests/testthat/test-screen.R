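# Motif models, protein/read screening, classification, query fragments.

test_that("motif models validate their thresholds", {
  m <- farRedMotif()
  expect_equal(m@motif, "VIPEDV")
  expect_equal(m@minMatches, 5L)
  expect_equal(whiteLightMotif()@minMatches, 4L)
  expect_error(motifModel("VIP"), class = "error")          # too short
  expect_error(motifModel("VIPEDV", minMatches = 2L))       # below half
})

test_that("protein scanning honours thresholds and never matches X", {
  h <- scanProtein("AAVIPEDVAA", farRedMotif())
  expect_equal(nrow(h), 1)
  expect_equal(h$position, 3L)
  expect_equal(h$score, 1)

  h2 <- scanProtein("VIPQDV", farRedMotif())
  expect_equal(h2$matches, 5L)

  # X never counts as a match, even where the motif expects any residue
  expect_equal(nrow(scanProtein("VIXXDV", farRedMotif())), 0)
  expect_equal(nrow(scanProtein("VIP", farRedMotif())), 0)  # too short
})

test_that("protein scanning equals the naive sliding-window oracle", {
  set.seed(51)
  for (rep in 1:20) {
    prot <- randomProtein(sample(30:200, 1))
    # plant a decayed motif in half the cases
    if (rep %% 2) {
      at <- sample(nchar(prot) - 6, 1)
      substr(prot, at, at + 5) <- "VIPQDV"
    }
    got <- scanProtein(prot, farRedMotif())
    want <- oracleScan(prot, "VIPEDV", 5)
    if (is.null(want)) {
      expect_equal(nrow(got), 0)
    } else {
      expect_equal(got$position, want$position)
      expect_equal(got$matches, want$matches)
    }
  }
})

test_that("six-frame read screening finds motif codons on either strand", {
  set.seed(52)
  codons <- list(V = c("GTT", "GTC", "GTA", "GTG"), I = c("ATT", "ATC"),
                 P = c("CCT", "CCA"), E = c("GAA", "GAG"),
                 D = c("GAT", "GAC"))
  encode <- function(aa) vapply(strsplit(aa, "")[[1]], function(a)
    sample(codons[[a]], 1), "")
  for (rep in 1:10) {
    motifNt <- paste(encode("VIPEDV"), collapse = "")
    off <- sample(0:2, 1)  # shift into frame +1/+2/+3
    lead <- randomDna(30 + off)
    read <- substr(paste0(lead, motifNt, randomDna(60)), 1, 100)
    hits <- screenReads(c(r1 = read), farRedMotif())
    expect_gte(nrow(hits), 1)
    expect_true(sprintf("%+d", off + 1) %in% hits$frame)
    # reverse-complemented read hits on the corresponding minus frame
    rcHits <- screenReads(c(r1rc = revComp(read)), farRedMotif())
    expect_gte(nrow(rcHits), 1)
    expect_true(any(startsWith(rcHits$frame, "-")))
    expect_setequal(rcHits$matched, hits$matched)
  }
  # motif split across the read end: no call
  motifNt <- paste(encode("VIPEDV"), collapse = "")
  broken <- paste0(randomDna(92), substr(motifNt, 1, 8))
  hitsB <- screenReads(c(rb = broken), farRedMotif())
  expect_true(is.null(hitsB) || nrow(hitsB) == 0)
})

test_that("classification follows motif and cysteine evidence", {
  # synthetic proteins with planted signatures
  frProt <- c(q = paste0(randomProtein(50), "VIPEDV", randomProtein(50)))
  wlProt <- c(q = paste0(randomProtein(50), "ENACS", randomProtein(50)))
  both <- c(q = paste0(randomProtein(20), "VIPEDV", randomProtein(20),
                       "ENACS", randomProtein(20)))
  none <- c(q = strrep("G", 80))
  expect_equal(classifyApcE(frProt, "protein")$label, "FAR_RED")
  expect_equal(classifyApcE(wlProt, "protein")$label, "WHITE_LIGHT")
  expect_equal(classifyApcE(both, "protein")$label, "AMBIGUOUS")
  expect_equal(classifyApcE(none, "protein")$label, "NO_CALL")

  # cysteine rule on the family protein alignment
  fam <- smallFamily(seed = 9)
  paln <- familyProteins(fam)
  calls <- vapply(fam$classMap$id, function(id)
    classifyApcE(paln[id], "protein", refAlignment = paln,
                 refId = "target_01")$label, "")
  expect_equal(unname(calls[fam$classMap$class == "target"]),
               rep("FAR_RED", 6))
  expect_equal(unname(calls[fam$classMap$class == "background"]),
               rep("WHITE_LIGHT", 6))

  # conflicting evidence: far-red motif but cysteine present
  tweaked <- paln
  vp <- regexpr("VIPEDV", tweaked[["background_01"]], fixed = TRUE)
  substr(tweaked[["background_01"]],  # plant fr motif into a wl protein
         250, 255) <- "VIPEDV"
  # remove its genuine wl motif so only the conflict remains
  en <- regexpr("ENACS", tweaked[["background_01"]], fixed = TRUE)
  if (en > 0) substr(tweaked[["background_01"]], en, en + 4) <- "GGGGG"
  cl <- classifyApcE(tweaked["background_01"], "protein",
                     refAlignment = tweaked, refId = "target_01")
  expect_equal(cl$cysteine, "present")
  expect_equal(cl$label, "AMBIGUOUS")

  expect_error(classifyApcE(paln["target_01"], "protein",
                            refAlignment = paln, refId = "missing"),
               class = "fm_lookup_error")

  # DNA route: full gene classified through six-frame translation
  g <- as.character(fam$ungapped)["target_02"]
  expect_equal(classifyApcE(g, "DNA")$label, "FAR_RED")
})

test_that("query fragments are 46 residues, centred, and truncate gracefully", {
  prot <- paste0(randomProtein(203), "VIPEDV", randomProtein(91))
  hit <- scanProtein(prot, farRedMotif())
  frag <- extractQueryFragment(prot, hit)
  expect_equal(nchar(frag), 46)
  expect_match(frag, "VIPEDV", fixed = TRUE)
  # roughly centred: motif midpoint near fragment midpoint
  at <- as.integer(regexpr("VIPEDV", frag, fixed = TRUE))
  expect_true(abs((at + 2.5) - 23.5) <= 1)

  shortP <- paste0("VIPEDV", randomProtein(24))
  hs <- scanProtein(shortP, farRedMotif())
  expect_equal(extractQueryFragment(shortP, hs), shortP)  # whole protein

  edge <- paste0("VIPEDV", randomProtein(94))
  he <- scanProtein(edge, farRedMotif())
  fe <- extractQueryFragment(edge, he)
  expect_equal(nchar(fe), 46)
  expect_equal(substr(fe, 1, 6), "VIPEDV")  # shifted inward at the start
})

test_that("misclassification under heavy noise is dominated by NO_CALL and decay never forges the other motif", {
  set.seed(53)
  labels <- character(0)
  locusForged <- 0L
  for (sd in 1:60) {
    fam <- smallFamily(seed = sd, nTarget = 2, nBackground = 2,
                       geneLengthBp = 702)
    paln <- familyProteins(fam)
    # decay everything, planted motifs included, at rate 0.2
    aaAlpha <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
    decayed <- vapply(paln, function(p) {
      cc <- strsplit(p, "")[[1]]
      hit <- runif(length(cc)) < 0.2
      cc[hit] <- sample(aaAlpha, sum(hit), replace = TRUE)
      paste(cc, collapse = "")
    }, "")
    for (id in fam$classMap$id[fam$classMap$class == "target"]) {
      lab <- classifyApcE(decayed[id], "protein")$label
      labels <- c(labels, lab)
      # at the homologous locus itself the other motif must never appear
      locus <- substr(decayed[[id]], 204, 209)
      if (!is.null(oracleScan(locus, "ENACS", 4))) locusForged <- locusForged + 1L
    }
  }
  expect_equal(locusForged, 0L)
  wrong <- labels[labels != "FAR_RED"]
  if (length(wrong))
    expect_equal(names(which.max(table(wrong))), "NO_CALL")
  expect_gt(mean(labels == "FAR_RED" | labels == "NO_CALL"), 0.9)
})
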