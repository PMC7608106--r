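# Synthetic family generator: determinism, planted structure, reads.

test_that("families are byte-identical under a seed and leave no RNG trace", {
  f1 <- generateFamily(familySpec(nTarget = 4, nBackground = 4, seed = 99))
  f2 <- generateFamily(familySpec(nTarget = 4, nBackground = 4, seed = 99))
  expect_identical(as.character(f1$alignment), as.character(f2$alignment))
  f3 <- generateFamily(familySpec(nTarget = 4, nBackground = 4, seed = 100))
  expect_false(identical(as.character(f1$alignment),
                         as.character(f3$alignment)))
  # global RNG state is untouched
  set.seed(1); before <- .Random.seed
  invisible(generateFamily(familySpec(nTarget = 2, nBackground = 2,
                                      seed = 5)))
  expect_identical(.Random.seed, before)
})

test_that("planted structure is where the coordinates say it is", {
  fam <- smallFamily(seed = 12)
  aln <- as.character(fam$alignment)
  tr <- fam$truth
  for (id in names(aln)) {
    prot <- translateFrame(aln[[id]], 1)
    res <- substr(prot, 204, 209)
    if (grepl("target", id)) {
      expect_equal(res, "VIPEDV")
      expect_false(substr(prot, 217, 217) == "C")
    } else {
      expect_equal(substr(res, 1, 5), "ENACS")
      expect_equal(substr(prot, 217, 217), "C")
    }
    # universal block identical across every sequence
    expect_equal(substr(aln[[id]], tr$universalStart, tr$universalEnd),
                 substr(aln[[1]], tr$universalStart, tr$universalEnd))
  }
  expect_error(familySpec(geneLengthBp = 600),
               class = "fm_validation_error")
})

test_that("zero substitution rate collapses each class onto its ancestor", {
  fam <- smallFamily(seed = 13, subRate = 0)
  cls <- familyClassSeqs(fam)
  expect_length(unique(cls$target), 1)
  expect_length(unique(cls$background), 1)
  pr <- familyProfiles(fam)
  isl <- discriminativeIslands(pr$target, pr$background)
  expect_gt(nrow(isl), 0)
  expect_true(isl$start[1] <= fam$truth$islandEnd &&
              isl$end[1] >= fam$truth$islandStart)
})

test_that("codon deletions appear as consistent gap columns", {
  fam <- smallFamily(seed = 14, nTarget = 8, nBackground = 8,
                     indelRate = 1)
  aln <- as.character(fam$alignment)
  expect_true(all(nchar(aln) == 2270))
  gapped <- grepl("-", aln, fixed = TRUE)
  expect_true(any(gapped))
  runs <- regmatches(aln[gapped], gregexpr("-+", aln[gapped]))
  expect_true(all(nchar(unlist(runs)) %% 3 == 0))
  # planted blocks are never deleted
  tr <- fam$truth
  for (s in aln)
    expect_false(grepl("-", paste0(
      substr(s, tr$islandStart, tr$islandEnd),
      substr(s, tr$cysStart, tr$cysEnd),
      substr(s, tr$universalStart, tr$universalEnd)), fixed = TRUE))
})

test_that("default families classify perfectly across seeds", {
  for (sd in 1:20) {
    fam <- smallFamily(seed = sd, nTarget = 4, nBackground = 4)
    paln <- familyProteins(fam)
    calls <- vapply(fam$classMap$id, function(id)
      classifyApcE(paln[id], "protein", refAlignment = paln,
                   refId = "target_01")$label, "")
    truth <- ifelse(fam$classMap$class == "target", "FAR_RED",
                    "WHITE_LIGHT")
    expect_equal(unname(calls), truth, info = paste("seed", sd))
  }
})

test_that("read sets cover the motif, balance strands, and decay under noise", {
  fam <- smallFamily(seed = 15, nTarget = 4, nBackground = 2)
  # binomial coverage argument: a read covers the 18 motif bases when it
  # starts within [islandEnd - 99, islandStart]; at 30x / 100 bp that
  # window is hit with probability > 0.999 per gene
  reads <- generateReads(fam, coverage = 30, errorRate = 0, seed = 2)
  hits <- screenReads(reads, farRedMotif())
  hitSrc <- unique(sub("^.*\\|src=([^|]+)\\|.*$", "\\1", hits$id))
  targets <- grep("target", names(fam$ungapped), value = TRUE)
  expect_true(all(targets %in% hitSrc))

  # strand balance over a large sample
  strands <- sub("^.*strand=", "", names(reads))
  expect_gt(mean(strands == "+"), 0.45)
  expect_lt(mean(strands == "+"), 0.55)

  # determinism
  r2 <- generateReads(fam, coverage = 30, errorRate = 0, seed = 2)
  expect_identical(as.character(reads), as.character(r2))

  # saturated noise wipes the motif signal out
  noisy <- generateReads(fam, coverage = 10, errorRate = 1, seed = 3)
  nh <- screenReads(noisy, farRedMotif())
  expect_lt(if (is.null(nh)) 0 else nrow(nh), 5)

  expect_error(generateReads(fam, readLengthBp = 5000),
               class = "fm_validation_error")
})

test_that("error-free reads fully covering the motif are always recovered", {
  fam <- smallFamily(seed = 16, nTarget = 3, nBackground = 1)
  ug <- as.character(fam$ungapped)
  ug <- ug[grep("target", names(ug))]
  tr <- fam$truth
  # construct reads that cover the motif codons at every feasible offset
  for (id in names(ug)) {
    for (start in seq(tr$islandEnd - 99, tr$islandStart, by = 7)) {
      plus <- substr(ug[[id]], start, start + 99)
      expect_gte(nrow(screenReads(setNames(plus, "p"), farRedMotif())), 1)
      expect_gte(nrow(screenReads(setNames(revComp(plus), "m"),
                                  farRedMotif())), 1)
    }
  }
})
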