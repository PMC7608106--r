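# Independent brute-force oracles. These deliberately share no code with
# the package internals: IUPAC sets come straight from Biostrings'
# published table, and every scan is a plain position-by-position loop.

oracleIupacSet <- function(sym) strsplit(Biostrings::IUPAC_CODE_MAP[[sym]], "")[[1]]

oracleExpand <- function(oligo) {
  sets <- lapply(strsplit(oligo, "")[[1]], oracleIupacSet)
  out <- ""
  for (s in sets) out <- as.vector(outer(out, s, paste0))
  sort(out)
}

oracleWallace <- function(concrete) {
  cc <- strsplit(concrete, "")[[1]]
  2 * sum(cc %in% c("A", "T")) + 4 * sum(cc %in% c("G", "C"))
}

# naive per-position IUPAC-intersection site scan over both strands
oracleSites <- function(template, core, maxMismatch, clampLen) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R",
            S = "S", W = "W", K = "M", M = "K", B = "V", V = "B",
            D = "H", H = "D", N = "N")
  rc <- function(s) paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
  tc <- strsplit(template, "")[[1]]
  n <- length(tc); m <- nchar(core)
  hits <- NULL
  for (strand in c("+", "-")) {
    q <- strsplit(if (strand == "+") core else rc(core), "")[[1]]
    # on the minus strand the primer core's 3' end maps to the LEFT end
    clampIdx <- if (strand == "+") (m - clampLen + 1):m else 1:clampLen
    for (s in seq_len(max(n - m + 1, 0))) {
      mism <- vapply(seq_len(m), function(j)
        length(intersect(oracleIupacSet(q[j]),
                         oracleIupacSet(tc[s + j - 1]))) == 0, TRUE)
      if (sum(mism) <= maxMismatch && !any(mism[clampIdx]))
        hits <- rbind(hits, data.frame(strand = strand, start = s,
                                       mismatches = sum(mism)))
    }
  }
  hits
}

oracleAmplify <- function(template, fwCore, rvCore, sizeBounds,
                          maxMismatch, clampLen) {
  fw <- oracleSites(template, fwCore, maxMismatch, clampLen)
  rv <- oracleSites(template, rvCore, maxMismatch, clampLen)
  out <- NULL
  addPairs <- function(plus, minus, lenPlus, lenMinus) {
    if (is.null(plus) || is.null(minus)) return()
    for (i in seq_len(nrow(plus))) for (j in seq_len(nrow(minus))) {
      st <- plus$start[i]; en <- minus$start[j] + lenMinus - 1
      len <- en - st + 1
      if (en >= st + lenPlus && len >= sizeBounds[1] && len <= sizeBounds[2])
        out <<- rbind(out, data.frame(start = st, end = en, length = len))
    }
  }
  addPairs(fw[fw$strand == "+", ], rv[rv$strand == "-", ],
           nchar(fwCore), nchar(rvCore))
  addPairs(rv[rv$strand == "+", ], fw[fw$strand == "-", ],
           nchar(rvCore), nchar(fwCore))
  if (is.null(out)) return(out)
  unique(out[order(out$length, out$start), ])
}

oracleScan <- function(protein, motifStr, minMatches) {
  pc <- strsplit(protein, "")[[1]]
  mc <- strsplit(motifStr, "")[[1]]
  hits <- NULL
  for (s in seq_len(max(length(pc) - length(mc) + 1, 0))) {
    k <- sum(pc[s:(s + length(mc) - 1)] == mc & mc != "X")
    if (k >= minMatches)
      hits <- rbind(hits, data.frame(position = s, matches = k))
  }
  hits
}

oraclePDist <- function(a, b, alphabet = "DNA") {
  ok <- if (alphabet == "DNA") c("A", "C", "G", "T")
        else setdiff(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], character(0))
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  n <- 0; d <- 0
  for (i in seq_along(ca)) {
    if (ca[i] %in% ok && cb[i] %in% ok) {
      n <- n + 1
      if (ca[i] != cb[i]) d <- d + 1
    }
  }
  c(dist = if (n > 0) d / n else NaN, comparable = n)
}

# exhaustive island scan applying the stated window predicate
oracleIslands <- function(tp, bp, windowLen, minCons, minDiscrim, maxGap) {
  nc <- profileLength(tp)
  rows <- NULL
  for (s in seq_len(nc - windowLen + 1)) {
    idx <- s:(s + windowLen - 1)
    okCols <- all(conservation(tp)[idx] >= minCons) &&
      all(gapFraction(tp)[idx] <= maxGap) &&
      all(gapFraction(bp)[idx] <= maxGap)
    if (!okCols) next
    differs <- consensus(tp)[idx] != consensus(bp)[idx]
    if (mean(differs) < minDiscrim) next
    score <- mean(vapply(idx, function(j)
      1 - symbolFreq(bp, consensus(tp)[j], j), 0))
    rows <- rbind(rows, data.frame(
      start = s, end = s + windowLen - 1,
      targetConservation = min(conservation(tp)[idx]),
      discrimScore = score))
  }
  if (is.null(rows)) return(rows)
  rows[order(-rows$discrimScore, -rows$targetConservation, rows$start), ]
}

randomDna <- function(n, letters = c("A", "C", "G", "T"))
  paste(sample(letters, n, replace = TRUE), collapse = "")

randomIupac <- function(n)
  paste(sample(names(Biostrings::IUPAC_CODE_MAP), n, replace = TRUE,
               prob = c(rep(4, 4), rep(1, 11))), collapse = "")

randomProtein <- function(n)
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n,
               replace = TRUE), collapse = "")
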