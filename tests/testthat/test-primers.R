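# Degenerate primer construction, Tm, tags, homology check, pair design.

test_that("degenerate consensus covers floored base sets and is monotone in the floor", {
  p <- buildProfile(c(a = strrep("A", 8), b = strrep("A", 8)))
  expect_equal(consensusDegenerate(p, 1, 8, freqFloor = 0.1),
               strrep("A", 8))
  # 50/50 C/T column gives Y (= C/T)
  p2 <- buildProfile(c(a = strrep("C", 8), b = strrep("T", 8)))
  expect_equal(consensusDegenerate(p2, 1, 8, freqFloor = 0.1),
               strrep("Y", 8))
  set.seed(31)
  for (rep in 1:10) {
    aln <- setNames(vapply(1:10, function(i) randomDna(8), ""),
                    paste0("s", 1:10))
    pr <- buildProfile(aln)
    floors <- c(0.05, 0.1, 0.2, 0.3, 0.5)
    degs <- vapply(floors, function(fl) oligoDegeneracy(
      consensusDegenerate(pr, 1, 8, freqFloor = fl, cap = 1e6)), 0)
    expect_true(all(diff(degs) <= 0))
  }
  expect_error(consensusDegenerate(p2, 1, 8, freqFloor = 0.1, cap = 1),
               class = "fm_validation_error")
})

test_that("Wallace Tm bounds agree with exhaustive expansion", {
  expect_equal(unname(tmRange("ACGTAC")), c(18, 18))  # 2*3 + 4*3
  # spec'd mini-example, via the unchecked internal (length < 6)
  expect_equal(unname(farmarker:::.tmRangeUnchecked("AY")), c(4, 6))
  set.seed(32)
  for (i in 1:30) {
    core <- randomIupac(sample(6:12, 1))
    if (oligoDegeneracy(core) > 256) next
    tms <- vapply(oracleExpand(core), oracleWallace, 0)
    expect_equal(unname(tmRange(core)),
                 c(min(tms), max(tms)), info = core)
  }
  expect_error(tmRange("ACG"), class = "fm_validation_error")
  expect_error(tmRange(strrep("A", 40)), class = "fm_validation_error")
})

test_that("tags attach without touching core degeneracy or Tm", {
  core <- "GTNATHCCNGARGAYGT"
  p <- degeneratePrimer(core)
  tag <- strrep("CTGAA", 4)  # 20 bp
  pt <- attachTag(p, tag)
  expect_equal(nchar(primerTag(pt)), 20)
  expect_equal(primerSequence(pt), paste0(tag, core))
  expect_equal(primerDegeneracy(pt), primerDegeneracy(p))
  expect_equal(primerTm(pt), primerTm(p))
  expect_equal(attachTag(p, "")@core, p@core)  # empty tag: unchanged
  expect_error(attachTag(p, "AYG"), class = "fm_validation_error")
  expect_error(attachTag(p, strrep("A", 31)), class = "fm_validation_error")
})

test_that("tag homology scan finds the exact longest common substring", {
  bg <- c(g1 = "ACGTACGTTTGACCA", g2 = "TTTTTTTTTT")
  # tag equal to a background substring
  res <- tagBackgroundCheck("ACGTTTGA", bg, minReportLen = 4)
  expect_equal(res$longest, 8L)
  hit <- res$matches[res$matches$length == 8, ]
  expect_equal(hit$templateId, "g1")
  expect_equal(hit$templateStart, 5L)

  # quadratic longest-common-substring oracle over both strands
  lcsub <- function(a, b) {
    best <- 0
    for (i in seq_len(nchar(a))) for (j in seq_len(nchar(b))) {
      k <- 0
      while (i + k <= nchar(a) && j + k <= nchar(b) &&
             substr(a, i + k, i + k) == substr(b, j + k, j + k)) k <- k + 1
      best <- max(best, k)
    }
    best
  }
  set.seed(33)
  for (rep in 1:8) {
    tag <- randomDna(12)
    bg2 <- c(x = randomDna(60), y = randomDna(60))
    want <- max(vapply(bg2, function(s)
      max(lcsub(tag, s), lcsub(revComp(tag), s)), 0))
    expect_equal(tagBackgroundCheck(tag, bg2)$longest, want)
  }
  expect_error(tagBackgroundCheck("ACGT", character(0)),
               class = "fm_validation_error")
})

test_that("pair design honours product size, universality and Tm constraints", {
  fam <- smallFamily(seed = 3, nTarget = 10, nBackground = 10)
  pr <- familyProfiles(fam)
  isl <- discriminativeIslands(pr$target, pr$background)
  uw <- c(fam$truth$universalStart, fam$truth$universalEnd)
  tmpl <- familyClassSeqs(fam)$target[1]

  pair <- designPair(isl[1, ], pr$target, pr$background, uw, tmpl,
                     fwTag = strrep("TA", 10), rvTag = strrep("GA", 10))
  expect_s4_class(pair, "PrimerPair")
  expect_true(abs(pairProductRange(pair)[["min"]] - 1200) <= 1200 * 0.05)
  expect_lte(pairDeltaTm(pair), 6)
  expect_equal(nchar(primerTag(pairForward(pair))), 20)

  # infeasible product window
  expect_error(
    designPair(isl[1, ], pr$target, pr$background, uw, tmpl,
               productRange = c(10, 20)),
    class = "fm_design_error")
  # unattainable annealing match
  err <- tryCatch(
    designPair(isl[1, ], pr$target, pr$background, uw, tmpl,
               maxDeltaTm = -1),
    error = identity)
  expect_s3_class(err, "fm_design_error")
  expect_match(conditionMessage(err), "deltaTm")
  # a window that is poorly conserved must be refused as non-universal
  noisy <- smallFamily(seed = 4, nTarget = 8, nBackground = 8,
                       subRate = 0.4)
  npr <- familyProfiles(noisy)
  nisl <- data.frame(start = noisy$truth$islandStart,
                     end = noisy$truth$islandEnd)
  err2 <- tryCatch(
    designPair(nisl, npr$target, npr$background, c(100, 117),
               familyClassSeqs(noisy)$target[1]),
    error = identity)
  expect_s3_class(err2, "fm_design_error")
  expect_match(conditionMessage(err2), "not conserved")
})

test_that("designed forward primers are perfectly specific on the family", {
  for (sd in c(2, 9)) {
    fam <- smallFamily(seed = sd, nTarget = 12, nBackground = 12)
    pair <- familyPair(fam)
    fw <- pairForward(pair)
    ug <- as.character(fam$ungapped)
    for (id in names(ug)) {
      sites <- findPrimerSites(setNames(ug[id], id), fw, maxMismatch = 0)
      perfect <- sum(sites$mismatches == 0)
      if (startsWith(id, "target")) {
        expect_gte(perfect, 1)
      } else {
        loose <- findPrimerSites(setNames(ug[id], id), fw,
                                 maxMismatch = 2)
        expect_equal(nrow(loose), 0)
      }
    }
  }
})
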