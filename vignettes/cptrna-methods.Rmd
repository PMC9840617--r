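---
title: "Methods: chloroplast tRNA census, anomalies, spacers, fragments, introns and evolution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chloroplast tRNA census, anomalies, spacers, fragments, introns and evolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cptrna)
```

# Scope and record model

`cptrna` analyses annotated transfer RNA genes of plastid genomes. It does
not predict tRNA genes — that is the job of covariance-model and
heuristic annotators (tRNAscan-SE, Aragorn, GeSeq) whose outputs the
package parses. Everything downstream operates on one normalized record
model: a tRNA gene with 0-based half-open forward-strand coordinates, an
isotype (the 20 standard amino-acid identities plus the organellar
specials fMet, Ile2, Sec, Pyl and suppressor), an RNA-alphabet anticodon
of length 2–4, optional unspliced/mature sequences, gene-relative intron
intervals and a source tag. All parsers convert coordinates and alphabets
at the boundary; malformed rows are logged and skipped rather than
aborting a 5,000-genome run.

Multi-annotator calls for the same locus are merged by reciprocal
interval overlap (default fraction 0.9 on both intervals, same strand).
The merged record keeps the fields of the highest-precedence source —
`trnascan > geseq > aragorn` — because the special isotype vocabulary
(fMet, Ile2, Sup) used throughout the census is tRNAscan-SE's. Isotype
disagreements keep the winner but flag the record `discordant`. How the
original multi-annotator corroboration resolved disagreements is not
documented anywhere we could find, so the precedence rule is this
package's own, surfaced as an explicit parameter.

# The pooled anticodon census

The census pools records into (isotype, anticodon) counts. Two details
matter and are easy to get wrong:

* **Percentages are truncated, not rounded.** A cell's percentage is
  `100 * count / total` floored at the second decimal, with the table's
  own cell sum as denominator. The packaged pooled census sums to
  214,383, and under truncation its headline cells come out as
  5.47 (Met-CAU), 4.93 (Ile2-CAU), 0.33 (fMet-CAU), 5.13 (Ala-UGC) and
  4.98 (Ile-GAU); ordinary rounding would give 5.48, 4.93, 0.33, 5.14
  and 4.99. The truncation is implemented with integer division so no
  floating-point drift can flip a digit.
* **Absence and rarity use different aggregations.** An anticodon is
  *absent* when its count summed over all isotypes is zero (computed over
  the full 64-triplet space, zero-filled). *Rarity* is assessed per
  (isotype, anticodon) cell: two suppressor-UCA genes are a rare cell even
  though selenocysteine-UCA contributes another 204. This is the only
  reading under which the published rare list (UCA among the count-2
  anticodons) is internally consistent.

Isotype assignment reverse-complements the anticodon to its codon and
translates with NCBI genetic code table 11. Anticodons that would decode
stop codons resolve through a configurable special map — UCA to Sec, CUA
to Pyl, UUA to suppressor by default, each of the first two being a valid
suppressor assignment as well. CAU is intrinsically three-way ambiguous
(Met, initiator fMet, lysidine-modified Ile2); the annotator's call wins
when it names one of the specials, otherwise Met.

`rare_max` defaults to 25, covering every count on the published rare
list up to AAU (22) while excluding the borderline GAG (42);
`abundant_min_pct` defaults to 5.0, reproducing the four over-5% cells
(Met-CAU, Asn-GUU, Ala-UGC, Arg-ACG).

# Anticodon-length anomalies

Anticodons of length 2 and 4 are screened out before the census and
reported separately, so every record is accounted for exactly once.
For a quadruplet, all four single-base deletions are enumerated as parent
candidates; the preferred parent is the deletion at position 4. That
choice encodes the insertion-after-the-triplet model that explains the
observed quadruplets (GUU→GUUA, UGG→UGGG, GCU→GCUA, UAU→UAUG, AUA→AUAA);
a caller-supplied set of known anticodons can override it when exactly
one other candidate is actually observed. Duplets are reported with all
twelve single-insertion reconstructions and no preferred parent — a
two-letter anticodon space could not cover twenty amino acids, so duplets
are treated as likely nucleotide-loss artifacts, not functional states.

# Spacer tRNAs

The bacterial-type rRNA operon retained by plastids places tRNA genes in
the 16S–23S spacer. For every same-strand 16S/23S pair whose inner gap is
at most `max_operon_gap` (default 10 kb, which keeps rRNA copies from
distinct inverted repeats from pairing with each other), the pair is
oriented transcriptionally and the tRNAs *strictly contained* in the open
gap are reported in transcription order. Strict containment is the
definition of "between" here; no partial-overlap tolerance is applied
because none is defined anywhere authoritative. Operons with zero
contained tRNAs still produce calls — genomes without spacer tRNAs are a
result, not a parsing failure — and both inverted-repeat copies are
reported independently.

# tRFs and tiRNAs

Fragment length classes follow the two conventional windows: tRFs at
14–32 nt and tiRNA halves at 30–50 nt. The 30–32 nt overlap between the
printed windows is resolved in favour of tiRNA, because tiRNAs are
defined as the *longer* class; the effective windows are therefore 14–29
and 30–50. End classes are assigned against mature references: a prefix
match within `max_mismatch` substitutions is 5′, a suffix match 3′, the
smaller mismatch count wins when both match and prefix wins ties; a
fragment with no terminal match is tRF-1, with its containing reference
as parent when it occurs internally and no parent otherwise
(precursor-derived). `max_mismatch` defaults to 0 since the conserved
fragment sequences reported for plastomes are exact strings.

`conserved_motif()` returns the longest substring common to all
fragments (leftmost on the first fragment among equals, `NULL` below
`min_len = 10`). Inputs are normalized to RNA, so DNA-alphabet motifs
from the literature match directly.

# Group I intron consensus

Intron sequences are extracted from the unspliced gene over the recorded
intron intervals and summarized per isotype. The consensus aligns every
sequence globally to the longest one (Needleman–Wunsch, match +1,
mismatch −1, gap −2) and reads columns off in the reference frame,
dropping insertions relative to the reference. A column becomes a literal
when its majority base reaches `identity_threshold` (default 0.8 — a
commonly used strong-conservation cutoff; no threshold is stated with the
published table); other columns become wildcards, and consecutive
wildcards collapse to run-length tokens recording the min/max non-gap run
over the sequences. The rendered notation (`A-U-x-G-x_4_-U-x_2:5_`)
parses back losslessly; degenerate positions from transcribed reference
tables are kept as choice tokens (`A/G`).

Consensuses are clustered by average-linkage hierarchical clustering, cut
at `k = 4`. The pairwise distance treats wildcards as universal matches
and is computed from the best *ends-free* alignment (a wildcard-aware
longest-common-subsequence), normalized by the shorter consensus. A plain
global edit distance was rejected: published consensus lines are
truncated alignment blocks, and the glutamate consensus is essentially a
prefix of the threonine one (their first 15 tokens are identical and the
next 19 align with a single indel) — a length-normalized global distance
calls two such consensuses dissimilar, which contradicts both the shared
motif and their published co-grouping. Singleton clusters at the cut are
labelled `ungrouped`.

# Sequence evolution

Transitions are A↔G and C↔U; the transition/transversion ratio is the
plain count ratio pooled over all sequence pairs, reported as undefined
(not infinite) when no transversions are observed. This is deliberately
*not* a maximum-likelihood bias estimator; published ML bias values (e.g.
R = 13.71 for one isotype) are estimates of a different quantity under a
substitution model and are not comparable or targeted.

Distances are Kimura two-parameter,
`d = -1/2 ln((1-2P-Q) sqrt(1-2Q))`, with saturation raised as an error
rather than returned as infinity. K2P was chosen as the default backing
metric for the trees because the upstream aligner-internal identity
distances are unspecified; the choice is documented as this package's
own.

Neighbor joining follows the classic agglomeration: minimize the
Q-criterion, join, compute branch lengths from the standard formulas,
reduce the matrix. Ties in Q are broken lexicographically on the smallest
leaf label of each cluster so the output is fully deterministic; negative
branch-length estimates are clamped to zero with a warning. On additive
matrices NJ provably recovers the generating tree, which the test suite
exercises against random trees (topology via Robinson–Foulds distance 0,
path lengths to 1e-9) and cross-checks against an independent NJ
implementation. Bootstrap support resamples alignment columns with
replacement, rebuilds the tree per replicate and counts leaf
bipartitions; it is deterministic under a fixed seed.

# The synthetic cohort generator

The generator produces plastome-like annotation bundles — FASTA, GFF3, a
tRNAscan-SE-format table and a complete truth set — so that every
pipeline stage can be validated against known ground truth. Its defaults
are the study conditions the package is meant to emulate, chosen once:

* clade proportions of the 5,959-genome cohort (Eudicot 64%, Monocot
  20%, Algae 5%, ...);
* per-clade mean tRNA counts (Monocot 37.8, Protist 29.5, Algae 30.12,
  others ≈36; dispersion sd 3, normal, rounded);
* plastome-typical GC targets (0.32–0.41 by clade);
* the pooled census as the anticodon sampling profile, so synthetic
  censuses resemble the real pooled table;
* gene bodies on a 72-nt scaffold with the anticodon at 0-based offset
  34 (canonical positions 35–37);
* introns drawn by instantiating the per-isotype consensus fixture
  (wildcards sampled uniformly at the genome's GC), inserted 3′ of the
  anticodon after base 38, the canonical plastid tRNA intron position;
* quadruplet anomalies built by appending a sampled base at position 4
  of a sampled triplet (so the planted parent is recoverable), duplets by
  deleting one base;
* parasite-mode genomes drawing 5–9 genes from the 14-anticodon
  survivor repertoire, with no rRNA operon (consistent with the absence
  of spacer tRNAs from such genomes);
* planted fragments cut from the genomes' own mature tRNAs with their
  declared end relationship; motif-bearing families (the internal 19-mer
  of glutamate tRFs, the 5′ 22-mer of glycine tRFs) force the reference
  base flanking the motif apart across references, so the longest common
  substring is the motif *exactly*, not the motif plus a lucky shared
  base.

Everything is deterministic given the seed. What the generator does *not*
emulate: quadripartite genome architecture beyond the single rRNA operon,
secondary structure and modification chemistry, annotator disagreement
noise, and sequencing error. Passing the recovery suite therefore shows
the pipeline is faithful to its record semantics — not that annotators
are accurate on real plastomes.

# Problem sizes and numerical choices

The validation suite runs at desk scale, chosen to keep estimator noise
well inside the asserted tolerances: the cohort-recovery check uses 50
genomes (~1,800 genes); NJ recovery uses 100 random 5–8-taxon additive
matrices; the transition/transversion estimator is checked on 1,000
simulated pairs of 100 sites (≈10,000 substitutions, giving a ratio
standard error near 0.1 against a ±10% band); the correlation estimator
on cohorts of 2,000 (standard error ≈0.02 against a ±0.05 band).
Cohort-scale published totals (215,966 pooled genes, 91 quadruplet
species, 55 tRFs, 244 tiRNAs, the monocot GC correlation r = 0.362)
require the original 5,959 NCBI accessions and are deliberately not
reproduction targets; the corresponding machinery is validated by the
property checks above instead.

Two transcription notes on the packaged census fixture: the in-text
pooled total (215,966) exceeds the printed cell sum (214,383); the
fixture follows the printed cells, and all percentage checks are made
against the cell sum. The running text also quotes a "UCG" spacer-tRNA
percentage of 5.13 where the printed alanine row carries that count under
UGC; this is treated as a typo for UGC and left unaltered in the fixture.
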