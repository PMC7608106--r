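---
title: "Detecting far-red cyanobacteria with the apcE2 marker: methods and design"
author: "farmarker"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting far-red cyanobacteria with the apcE2 marker}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(farmarker)
```

## The scientific problem

Far-Red Light Photoacclimation (FaRLiP) lets a scattered minority of
cyanobacteria photosynthesise beyond ~700 nm by remodelling their
photosystems and phycobilisomes around chlorophyll *f*. Because the
trait is spread across most major cyanobacterial clades, a simple
taxonomic marker such as 16S rRNA cannot detect it; culture-based
screening under far-red light takes weeks and misses everything that
will not grow. What does work is a *functional* marker gene: `apcE2`,
the far-red paralog of the phycobilisome linker, occurs exclusively
inside FaRLiP gene clusters. At the protein level, far-red ApcE2 carries
a conserved VIPEDV-like motif at residues 204–209 (numbering follows the
*Chroococcidiopsis thermalis* sequence) where white-light ApcE1 carries
an ENACS-like motif, and ApcE2 lacks the phycocyanobilin-binding
cysteine at residue 217 that ApcE1 retains — a substitution with direct
physiological meaning, since non-covalent bilin binding red-shifts the
linker's absorbance.

`farmarker` turns this observation into a reproducible computational
pipeline: find class-discriminative conserved windows in a two-class
alignment, design tagged degenerate primers against them, predict
amplicons in silico, screen contigs and short reads for the motif by
six-frame translation, and place recovered fragments among references by
distance.

## Discriminative islands

Both classes must come from one merged alignment so that columns
correspond; the package deliberately does not align (alignment quality
is an input decision, not something to hide inside a detector).
`buildProfile()` summarises each class per column: symbol frequencies
over non-gap symbols, gap fraction, consensus, and conservation defined
as the majority-symbol frequency. Majority frequency, not entropy, is
used because it is directly thresholdable and mirrors the
conserved/distinct judgement it automates; offering a second metric
would add a knob without adding power.

`discriminativeIslands()` slides a fixed window and keeps those where
every column is conserved in the target class
(`minTargetConservation`, default 0.8), gap-poor in both classes
(`maxGapFraction`, default 0.2), and where at least `minDiscrimCols`
(default 0.5) of the columns have a target consensus that differs from
the background consensus. The discrimination score of a window is the
mean of `1 − f_bg(target consensus)` over its columns — 1 when the
background never shows the target's consensus symbol. Ranking is by
score, then minimum within-target conservation, then leftmost start, so
output order is fully deterministic. Defaults are 18 columns for DNA
(roughly a primer core) and 6 for protein (the motif length). The
thresholds are engineering defaults, exposed as arguments, because the
original selection step was visual and published no numbers.

One geometric fact discovered during testing is worth recording: the
VIPEDV and ENACS codon blocks share their first base (V and E both start
with G), so the island's first column can never discriminate and the
top-ranked window systematically slides one column off the planted
block into flanking sequence. This is correct behaviour of the stated
score, and it is why primer design must cover observed flanking
variation (next section).

## Primer design

`consensusDegenerate()` builds an IUPAC core by taking, at each column,
the set of bases whose frequency reaches `freqFloor` (the consensus base
is always included). Lowering the floor weakly increases degeneracy.
Three named presets echo a low/medium/high degeneracy ladder:

| preset | freqFloor | cap  |
|--------|-----------|------|
| low    | 0.25      | 64   |
| medium | 0.05      | 512  |
| high   | 0.00      | 4096 |

`medium` is the default. Its floor of 0.05 is chosen so that, with the
default 20-sequence target class, every *observed* base (minimum
frequency 1/20) is covered: a designed forward primer then has a
perfect binding site in every target sequence. A floor of 0.1 provably
breaks that guarantee whenever a singleton variant falls inside the
selected window — which, per the geometry above, it regularly does.

Melting temperatures use the Wallace rule, `Tm = 2(A+T) + 4(G+C)`,
evaluated on the core only. Because the rule depends only on GC count,
the Tm range of a degenerate core follows per position (a symbol whose
set lies within {G,C} always contributes 4, one disjoint from {G,C}
always 2, mixed symbols either), with no enumeration.
Nearest-neighbour thermodynamics are out of scope: the quantity being
controlled is the *match* between the two primers (`maxDeltaTm`,
default 6 °C), for which a consistent simple rule suffices.

Tags — 20 bp concrete 5′ extensions that improve product recovery — are
stored separately from the core; they change neither degeneracy nor Tm.
`tagBackgroundCheck()` screens a candidate tag against background
sequences by exact longest-common-substring on both strands:
deterministic, dependency-free, and sufficient to flag mispriming
seeds, which is all a homology screen of a 20-mer needs.

`designPair()` assembles the pair: forward core from the island on the
target profile; reverse core as the reverse complement of the
degenerate consensus of a window that must be conserved in *both*
classes (that is what "universal" means — the constraint is enforced
and refusal names the failing class). The predicted product runs from
the island start to the universal-window end on a named template,
~1.2 kb in the default geometry.

## In-silico PCR

Primer–template matching is IUPAC-intersection based (a position
matches iff the two base sets intersect), with at most `maxMismatch`
failures (default 2) and an exact-match 3′ clamp of `clampLen` bases
(default 3) — degenerate-PCR practice, since 3′-terminal mismatches
abolish extension. Both strands are scanned; `amplify()` reports every
convergent site combination whose product length lies within bounds,
with no nesting filter, sorted deterministically. Coordinates are
1-based inclusive throughout the package.

## Motif screening and classification

"VIPEDV-like" and "ENACS-like" are quantified as count thresholds —
at least 5/6 and 4/5 identical positions respectively — because the
source material never defines "like"; both the per-position allowed
sets and the thresholds are configurable in `motifModel()`. `X` never
counts as a match.

`classifyApcE()` labels a sequence by the stronger of the two motifs'
best hits (score = matches/length). A strict "any hit of both motifs
means AMBIGUOUS" rule was tried first and rejected on arithmetic
grounds: with a ~750-residue translation there are ~750 windows, and a
chance ≥4/5 ENACS match occurs at ~2.7 × 10⁻⁵ per window — about 2 % of
far-red full-length genes would be called AMBIGUOUS for no biological
reason. Since the two motifs occupy homologous positions in real ApcE,
a genuine signature (score 1) should and does outweigh a chance partial
match elsewhere. Equal best scores are a genuine conflict and yield
`AMBIGUOUS`, unless the independent cysteine diagnostic is available to
break the tie. When a reference alignment containing the query is
supplied, the cysteine rule applies on top: a far-red call with
cysteine present (or white-light with cysteine absent) is demoted to
`AMBIGUOUS`. Motif-only calls are allowed because metagenomic fragments
often do not cover the cysteine column. DNA input is scanned in all six
frames (robust to miscalled gene starts); the call is made on the frame
with the best hit.

`screenReads()` six-frame translates whole read sets with one
Biostrings call per frame — per-read translation is two orders of
magnitude slower — and reports hits with frame and protein coordinate.
A read must contain the complete motif codons in one frame; there are
no partial-motif calls. `extractQueryFragment()` cuts the 46-residue
query fragment centred on a motif hit (shifted inward at sequence
ends), the geometry used to search unassembled ~100 bp reads.

## Placement

Placement is deliberately distance-based: p-distance plus
neighbor-joining gives deterministic, dependency-light clade-level
placement, which is the claim being supported (fragments carry enough
signal to land in the right clade); maximum-likelihood inference with
support values is out of scope. Columns with a gap or ambiguity symbol
in either sequence are excluded from distances, and a pair with fewer
than `minOverlap` comparable columns (default 100) is an error rather
than a NaN.

`placeFragment()` aligns the fragment semi-globally (fragment global,
reference local; +1/−1 match/mismatch, −2 per gap position) against
each reference's ungapped sequence — both strands for DNA — and maps it
into alignment columns via the best-scoring reference. All pairwise
distances, including reference–reference, are then computed over the
fragment-covered columns only, so every entry of the NJ matrix is on
one scale. NJ itself is delegated to `ape::nj()` (the standard
Saitou–Nei implementation); negative branch lengths, which NJ can
produce on non-additive input, are clamped to zero with the total
deficit recorded as a tree attribute. The sister group is read off the
tree rooted at the user-specified outgroup when given, otherwise at the
reference farthest from the fragment — an implicit-outgroup convention
that makes "sister group" well defined on an otherwise unrooted tree.

## The synthetic generator: what it emulates and what it does not

`generateFamily()` draws a random ancestral gene of sense codons
(default 2,270 bp) and derives two class ancestors: the target ancestor
gets the VIPEDV codons at residues 204–209 and a serine at 217; the
background ancestor first drifts away from the common ancestor at
`classDivergence` (default 0.15) per site and then gets ENACS codons at
residues 204–208 (the two motifs differ in length; the background's
residue 209 is left ancestral) and a cysteine at 217. The divergence
parameter encodes the fact that apcE1 and apcE2 are anciently diverged
paralog clades, not one pool of sequences differing only at the motif;
without it the synthetic classes would form a star phylogeny that no
placement method could separate. Each descendant then mutates
independently at `subRate` (default 0.05, uniform over the three
alternative bases — the simplest model that exercises the thresholds).
Planted columns never mutate. An 18 bp
universal block is planted immutably in *both* classes ending 1,200 bp
after the island start, reproducing the ~1.2 kb amplicon geometry; its
sequence is fixed (sense codons, Wallace Tm 52 °C, equal to the planted
forward core's Tm) because the method presupposes a universal region
against which a temperature-matched reverse primer exists — with a
random-GC block the ΔTm constraint would fail for a large fraction of
seeds, i.e. the generator would not emulate the structure the method
targets. Indels are off by default; when enabled they are codon-length
deletions rendered as gap columns, which keeps the merged alignment
consistent without re-aligning (insertions would require exactly the
alignment step the package declines to own).

`generateReads()` samples reads (default 100 bp) uniformly from both
strands at a requested coverage with independent per-base substitution
errors, recording provenance in the read ids. All randomness flows
through one seeded generator and the caller's RNG state is restored —
the same seed gives byte-identical output.

What the generator does **not** emulate: phylogenetic (tree-structured)
covariance between sequences, composition bias, transition/transversion
bias, length variation between paralogs, sequencing-error profiles
beyond uniform substitutions, and chimeric or contaminated reads.
Passing tests therefore demonstrate the pipeline's correctness and
discrimination logic under the stated geometry, not its performance on
real environmental data.

## Numerical choices and degenerate inputs

- Coordinates are 1-based inclusive; residue numbering counts non-gap
  reference symbols from 1, and columns where the reference is gapped
  map to the nearest preceding residue with a flag.
- Consensus ties break alphabetically; island ties break leftmost; NJ
  tie-breaking follows `ape`'s deterministic implementation.
- `U` is normalised to `T` on input; output always uses `T`. Gaps are
  legal only in alignment contexts; primer, PCR and translation
  operations reject them.
- Codons containing ambiguity translate to their amino acid when all
  expansions agree (`GCN` → `A`) and to `X` otherwise; stops are `*`.
- Frequencies in a profile column sum to 1 over non-gap symbols; an
  all-gap column has consensus `-` and conservation 0.
- Error families are typed conditions: validation/parse/lookup errors
  exit the CLI with 1, design-failure and insufficient-overlap errors
  with 2.

## Problem sizes used by the test-suite and acceptance script

The bundled checks run desk-scale replicates chosen to finish quickly
while keeping every estimate meaningful: oracle-equivalence suites use
~100+ random instances of up to 300 columns / 5 kb / 500 residues; NJ
correctness uses 100 random 5–8-taxon additive matrices; the end-to-end
recovery check sweeps 20 seeds of the default 20+20 family (the
acceptance script uses 12); placement runs against a 12-reference
subset spanning both clades, which is sufficient to decide the
sister-clade question the check asks.

## Known limitations

- The Wallace rule is a rough Tm model; absolute temperatures should
  not be read as annealing recommendations, only the matching matters.
- The tag homology check is exact-substring, not local alignment; tags
  with many near-matches but no exact seed will pass it.
- Distance placement reports clade-level affinity; it does not estimate
  support values, and long-branch effects are untreated.
- Classification of DNA relies on at least one clean reading frame over
  the motif; frameshifted pseudogenes produce `NO_CALL`.
- `apcE2` presence indicates FaRLiP capacity, not active chlorophyll
  *f* production; pseudogenes or divergent paralogs outside the design
  assumptions can mislead any marker-based method.
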