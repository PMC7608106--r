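# Sequence I/O and alphabet validation.
#
# Collections of sequences are plain Biostrings containers (DNAStringSet /
# AAStringSet) whose names are the record ids; parsing goes through
# Biostrings with an added validation pass that reports the offending
# record and position instead of a container-level error.

.ALPHABETS <- list(
  DNA     = strsplit("ACGTNRYSWKMBDHV", "")[[1L]],  # after U -> T
  protein = strsplit("ACDEFGHIKLMNPQRSTVWYX*", "")[[1L]]
)

# validate one sequence string; errors name the record and 1-based position
validateSeq <- function(seq, alphabet = c("DNA", "protein"),
                        allowGap = FALSE, what = "record") {
  alphabet <- match.arg(alphabet)
  ok <- .ALPHABETS[[alphabet]]
  if (allowGap) ok <- c(ok, "-")
  cc <- chars(seq)
  bad <- which(!(cc %in% ok))
  if (length(bad))
    fmValidationError(sprintf(
      "illegal %s symbol '%s' in %s at position %d",
      alphabet, cc[bad[1L]], what, bad[1L]))
  invisible(TRUE)
}

#' Read sequences from FASTA or FASTQ
#'
#' Reads a multi-record FASTA (wrapped or unwrapped) or 4-line FASTQ file
#' into a `DNAStringSet` or `AAStringSet` named by record id. Every record
#' is validated against the declared alphabet; for DNA, `U` is normalised
#' to `T` on input. FASTQ qualities are parsed and discarded (no quality
#' filtering is applied).
#'
#' @param path path to a FASTA or FASTQ file.
#' @param alphabet `"DNA"` (IUPAC nucleotide codes allowed) or `"protein"`.
#' @param format `"auto"` (by extension, falling back to first byte),
#'   `"fasta"` or `"fastq"`.
#' @param allowGap permit the alignment gap character `-` (for aligned
#'   FASTA input).
#' @return a named `DNAStringSet` or `AAStringSet`, input order preserved.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">a", "ACGU"), fa)
#' readSeqs(fa)  # "ACGT" after U -> T
#' @export
readSeqs <- function(path, alphabet = c("DNA", "protein"),
                     format = c("auto", "fasta", "fastq"),
                     allowGap = FALSE) {
  alphabet <- match.arg(alphabet)
  format <- match.arg(format)
  if (!file.exists(path))
    fmValidationError(paste0("file not found: ", path))
  if (format == "auto") {
    format <- if (grepl("\\.(fq|fastq)(\\.gz)?$", path, ignore.case = TRUE))
      "fastq"
    else if (grepl("\\.(fa|fasta|fna|faa|afa|aln)(\\.gz)?$", path,
                   ignore.case = TRUE))
      "fasta"
    else {
      first <- substr(readLines(path, n = 1L), 1L, 1L)
      if (identical(first, "@")) "fastq" else "fasta"
    }
  }
  raw <- tryCatch(
    Biostrings::readBStringSet(path, format = format),
    error = function(e) fmParseError(
      sprintf("failed to parse %s as %s: %s", path, format,
              conditionMessage(e))))
  ids <- sub("\\s.*$", "", names(raw))
  if (any(!nzchar(ids)))
    fmParseError(sprintf("empty record id (record %d) in %s",
                         which(!nzchar(ids))[1L], path))
  seqs <- toupper(as.character(raw))
  if (any(!nzchar(seqs)))
    fmParseError(sprintf("empty sequence for record '%s' in %s",
                         ids[which(!nzchar(seqs))[1L]], path))
  if (alphabet == "DNA") seqs <- chartr("U", "T", seqs)
  for (i in seq_along(seqs))
    validateSeq(seqs[i], alphabet, allowGap = allowGap,
                what = sprintf("record '%s'", ids[i]))
  out <- if (alphabet == "DNA") Biostrings::DNAStringSet(seqs)
         else Biostrings::AAStringSet(seqs)
  names(out) <- ids
  # keep any description after the first whitespace as metadata
  desc <- sub("^\\S+\\s*", "", names(raw))
  S4Vectors::metadata(out)$description <- setNames(desc, ids)
  out
}

#' Write sequences to FASTA
#'
#' @param x a named `XStringSet` or named character vector; ids must be
#'   unique and non-empty.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeSeqs <- function(x, path) {
  if (is.character(x)) x <- Biostrings::BStringSet(x)
  ids <- names(x)
  if (is.null(ids) || any(!nzchar(ids)))
    fmValidationError("all records must have non-empty ids")
  if (anyDuplicated(ids))
    fmValidationError(sprintf(
      "duplicate record id '%s': ids must be unique within one file",
      ids[anyDuplicated(ids)]))
  Biostrings::writeXStringSet(Biostrings::BStringSet(as.character(x)), path)
  invisible(path)
}

#' Translate a DNA sequence in one reading frame
#'
#' Frames `+1, +2, +3` read the given strand at offsets 0..2; frames
#' `-1, -2, -3` read the reverse complement likewise. A trailing partial
#' codon is dropped. Translation uses the standard genetic code (identical
#' to bacterial table 11 for sense codons); a codon containing ambiguity
#' symbols is translated to its amino acid when all of its expansions
#' agree (e.g. `GCN` -> `A`) and to `X` otherwise; stop codons become `*`.
#'
#' @param seq an ungapped DNA-IUPAC string.
#' @param frame integer in `c(1, 2, 3, -1, -2, -3)`.
#' @return the protein string (possibly empty).
#' @examples
#' translateFrame("ATGGCGA", 1)  # "MA", trailing base dropped
#' translateFrame("GCN", 1)      # "A"
#' @export
translateFrame <- function(seq, frame) {
  if (!frame %in% c(1L, 2L, 3L, -1L, -2L, -3L))
    fmValidationError("'frame' must be one of +1,+2,+3,-1,-2,-3")
  validateSeq(seq, "DNA", allowGap = FALSE, what = "sequence")
  s <- if (frame < 0) revComp(seq) else seq
  off <- abs(frame) - 1L
  n <- nchar(s) - off
  n <- n - n %% 3L
  if (n < 3L) return("")
  sub <- substr(s, off + 1L, off + n)
  as.character(Biostrings::translate(Biostrings::DNAString(sub),
                                     if.fuzzy.codon = "solve"))
}

#' Translate a set of DNA sequences in one reading frame
#'
#' Vector equivalent of [translateFrame()]: one Biostrings call for the
#' whole set, which is far cheaper than per-sequence translation when
#' screening thousands of reads.
#'
#' @param seqs named `DNAStringSet` or character vector (ungapped).
#' @param frame integer in `c(1, 2, 3, -1, -2, -3)`.
#' @return named character vector of protein strings (`""` where the
#'   frame leaves no complete codon).
#' @export
translateSet <- function(seqs, frame = 1L) {
  if (!frame %in% c(1L, 2L, 3L, -1L, -2L, -3L))
    fmValidationError("'frame' must be one of +1,+2,+3,-1,-2,-3")
  seqs <- toupper(asNamedChar(seqs))
  if (any(grepl("-", seqs, fixed = TRUE)))
    fmValidationError("translation requires ungapped sequence")
  dna <- Biostrings::DNAStringSet(seqs)
  if (frame < 0) dna <- Biostrings::reverseComplement(dna)
  off <- abs(frame) - 1L
  w <- Biostrings::width(dna)
  n <- pmax(w - off, 0L)
  n <- n - n %% 3L
  out <- setNames(character(length(seqs)), names(seqs))
  keep <- which(n >= 3L)
  if (length(keep)) {
    sub <- Biostrings::subseq(dna[keep], start = off + 1L,
                              width = n[keep])
    out[keep] <- as.character(Biostrings::translate(
      sub, if.fuzzy.codon = "solve"))
  }
  out
}

#' Translate all six reading frames
#'
#' @param seq an ungapped DNA-IUPAC string.
#' @return named character vector with elements `+1, +2, +3, -1, -2, -3`.
#' @export
sixFrameTranslate <- function(seq) {
  frames <- c(1L, 2L, 3L, -1L, -2L, -3L)
  setNames(vapply(frames, function(f) translateFrame(seq, f), ""),
           sprintf("%+d", frames))
}
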