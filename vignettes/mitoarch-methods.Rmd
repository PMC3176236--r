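---
title: "Methods: models, conventions and design choices in mitoarch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, conventions and design choices in mitoarch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitoarch)
```

mitoarch implements the recurring comparative analyses of animal
mitochondrial genome architecture. This vignette is the package's own
account of the underlying models, the conventions chosen where several were
defensible, and what the test suite does and does not demonstrate.

## Coordinates, strands and the annotation model

Annotations use 1-based, fully closed coordinates on the majority (J)
strand, matching the way mitogenome papers print their annotation tables.
Strands are `J`/`N` internally and `+`/`-` on disk. A `mito_annotation` is
a gene table plus genome length, circularity flag and optional J-strand
sequence; gene names are canonicalized onto the 37-label vocabulary
(`cox1..nad6`, `trnA..trnY` with `trnL1`=uag/`trnL2`=uaa and
`trnS1`=gcu/`trnS2`=uga, `rrnS`/`rrnL`). Features spanning the replication
origin are rejected: none occur in the shipped data, and supporting them
would push a split-interval representation through every downstream
consumer for no current benefit.

The spacer after gene *i* is `start[i+1] - end[i] - 1`; negative values are
overlaps. On a circular genome the last gene wraps to the first with gap
`(L - end_last) + (start_first - 1)`. The shipped proturan table declares
`1` in its wrap cell where this convention computes `0`, and declares a
trnC size of 54 where the coordinates imply 55; both cells are internally
inconsistent with the row's own coordinates (an end of 14490 would
reconcile them), so validation flags them rather than silently accepting
either reading. The control region is deliberately **not** a gene: it is
derived as the largest positive spacer, which keeps "where is the A+T-rich
region" a function of the annotation instead of an annotation entry that
could disagree with it.

`validate_annotation()` returns violations as data, never exceptions: an
annotation with a size typo is still an annotation, and surveys over many
genomes need to keep going.

## Strand asymmetry

AT-skew = (A − T)/(A + T), GC-skew = (G − C)/(G + C), AT content =
(A + T)/(A + C + G + T). The formulas are scale-free, so `skew_stats()`
accepts either raw counts or printed proportions. Zero denominators yield a
flagged `NA`. Values are never rounded internally; 3-decimal rounding is
presentation-layer only. Note that plugging 3-decimal printed frequencies
into the GC-skew formula gives 0.348 where full-sequence counts give 0.350
— agreement at the third decimal requires the actual counts, which is why
the per-gene report always recomputes from sequence.

Per-gene reports cover the 13 protein-coding and 2 rRNA genes and always
use the J-strand substring, regardless of coding strand: cross-genome skew
panels are comparable only if every value refers to the same physical
strand. A `coding_strand = TRUE` option exists but is off by default.
Ambiguity letters are excluded from numerators and denominators but retain
their positions in region lengths.

## Signed circular gene orders

A gene order is a circular sequence of (label, orientation) pairs read
along the J-strand, anchored at `cox1`; if the anchor is annotated on the N
strand the circle is reflected so that `cox1` reads J, making equality
rotation-invariant and independent of which strand a submitter called
majority. The two clade ground patterns are stored in this J-direction
reading. Pattern strings quoted in transcription direction for N-strand
blocks — `rrnL-trnL1-trnL2-nad1` — therefore appear reversed in storage
(`nad1, trnL2, trnL1, rrnL`, all N); the conversion is mechanical
(reverse the list, keep N orientations).

Adjacency (junction) checks ignore spacer lengths — a 4-nt gap still
counts as adjacent, since junction surveys care about gene neighborhood,
not spacer erosion — and accept either reading direction unless
`strand_sensitive = TRUE`. Classification of the *trnL2* pattern:
`pancrustacean` iff `cox1–trnL2–cox2` holds; `ancestral_arthropod` iff
`cox1–cox2` holds and *trnL2* (when present) lies on an arc between *rrnL*
and *nad1* whose interior contains only leucine tRNAs — the arc tolerance
deliberately accepts both `rrnL-trnL1-trnL2-nad1` and
`rrnL-trnL2-trnL1-nad1`, because a genome whose ribosomal block inverted
as a whole swaps the two leucine tRNAs relative to the reference reading,
and the biological claim ("*trnL2* is in the ancestral neighborhood, not at
the cox1/cox2 junction") is the same either way. Partial records carrying
only the *cox1/cox2* junction (amplicon-scale data) classify on that
junction alone; flags whose genes are absent stay `NA` and drop out of
survey denominators.

Breakpoints are signed circular adjacencies of one order absent from the
other, counting an adjacency as conserved when its reverse-complement
reading occurs; this makes the count symmetric and zero exactly for
rotation-equal circles.

Inverted-block detection maps each gene to its reference position and cuts
the circle into maximal runs of consecutive ±1 position steps (two adjacent
non-broken links can never disagree in direction, so runs are simply the
stretches between broken links). A reversed run whose members all flipped
orientation is a clean inverted block. Within order-preserved runs, an
isolated flipped gene is reported as a length-1 inversion — a single-gene
inversion is exactly a strand flip in place — while a stretch of two or
more consecutive flipped genes that kept their relative order is reported
under `strand_flips`, because no single inversion can produce it. This is
how the package expresses the both-views reading of a rearranged ribosomal
block: the block inversion is reported exactly, and the leucine-tRNA pair
that does not fit a clean inversion is reported alongside rather than
forced into one interpretation.

## One-step TDRL feasibility

In a tandem duplication–random loss event the block is duplicated in
tandem and one copy of each gene is lost, so the outcome reads: genes
retained in copy 1, in ancestral order, then genes retained in copy 2, in
ancestral order. An observed block is reachable in one event iff its
ancestral-index sequence is an increasing prefix followed by an increasing
suffix — equivalently, it has at most one descent. This is deliberately
**stronger** than "decomposable into two increasing subsequences"
(LDS ≤ 2): the index sequence 2,1,4,3 interleaves into {2,4} and {1,3} yet
is not a one-step outcome, because the two retained subsequences cannot
interleave — copy 1 precedes copy 2 physically. The test suite pins this
down by exhaustive agreement with the 2^n duplication-loss enumeration for
every permutation of n ≤ 7 (5,913 permutations). The witness returned is
the prefix/suffix split at the descent; orientation mismatches fail
immediately since TDRL never flips strands. No general minimal-scenario
inference is attempted (it is a hard combinatorial problem and the
single-event question is the scientifically posed one).

## Tandem repeat detection

The detector targets the clean head-to-tail arrays of mitochondrial
control regions: exact period, point substitutions, a fractional trailing
copy. For each period *p* in `min_period..max_period` (defaults 5–60 nt,
bracketing reported unit lengths) it marks positions with
`s[i] == s[i+p]`, merges TRUE-runs across short gaps (absolute gap ≤ 4, or
locally within `max_divergence`), and requires overall mismatch fraction ≤
`max_divergence` (default 0.2). Candidate boundaries are then refined
against the periodic extension of the region's own consensus with a
+1/−2 match/mismatch walk anchored at a unit boundary near the region
middle, placing each edge at the walk's score maximum (farther position
on ties). This pins edges to where the sequence genuinely continues the
repeat instead of wherever chance period-matches peter out — the step that
makes calls invariant under random flanking sequence.

Copy number is region length divided by period, rounded to 0.1 — the
resolution at which fractional copy numbers are conventionally reported —
and the trailing partial copy is counted only if it matches the consensus
prefix at ≥ 1 − `max_divergence`. Which copy is partial is not observable
from a single sequence; the package fixes the convention that the partial
copy trails. Consensus is per-column majority over full units, ties
alphabetical. Overlapping calls are resolved by longer array, then higher
identity at whole-percent grain (so sampling noise cannot promote a period
multiple), then smaller period; candidates whose span is essentially
covered by a divisor-period candidate, or whose consensus is itself
tandemly periodic at an allowed divisor, are dropped as disguised
multiples. Indels within units are out of scope: the detector performs no
alignment, and an array with an insertion will be split at the insertion
point.

The stem-loop score is a Nussinov-style dynamic program maximizing nested
base pairs (AU, GC, GU all weight 1, minimum hairpin loop 3). It is a
pairing-count proxy for stem-loop forming potential, explicitly not a
thermodynamic minimum-free-energy fold; the suite verifies it against
brute-force enumeration over all nested structures on short sequences.

## The cloverleaf model

`fit_cloverleaf()` is a structural classifier, not a tRNA detector: it
assumes its input is a tRNA (annotations come from upstream tools) and asks
which arms the sequence can form. It exhaustively enumerates boundary
placements within fixed windows — acceptor stem 5–7 bp with 0–1 nt 3'
overhang, optional DHU arm (stem 3–4 bp, loop 4–12 nt), anticodon arm
(stem 4–5 bp, loop fixed at 7 nt with the anticodon at loop positions
3–5), variable region 3–24 nt, optional TΨC arm (stem 3–5 bp, loop 3–9
nt) — scoring Watson–Crick and GU pairs equally and tolerating at most one
non-pairing position per stem. GU at full weight is a simplification; at
tRNA stem lengths a half-weight wobble changes almost no arm-presence
decisions while complicating the tie structure. Ties break toward more
arms present, then a longer acceptor stem, then the leftmost layout under
a fixed enumeration order, making the fit fully deterministic. Layouts
with equal score can differ in internal spacer placement, so exact
boundary recovery is only guaranteed when the generated layout is uniquely
optimal; arm presence — the scientific output — is what the recovery
property tests. A sequence with no acceptor stem of ≥ 5 positions is
reported `unfoldable` rather than raising, so batch runs over 22 annotated
tRNAs never abort.

Pairwise identity uses Needleman–Wunsch global alignment (match +1,
mismatch −1, gap −2, via Biostrings) with identity defined as matches over
alignment columns, reported to whole percent. The denominator choice
matters when indels occur and is recorded in the output, since
"percent identity" is otherwise ambiguous.

## The synthetic-data generator

The generator's defaults are the study conditions of a compact, extremely
AT-rich arthropod mitogenome: J-strand frequencies T 0.524, A 0.252,
G 0.151, C 0.073 (AT-skew −0.351, GC-skew 0.350), per-gene lengths from a
14.5-kb genome with strongly reduced tRNAs, and a control region carrying
a 10-bp unit in 11 exact copies flanked by 30 nt of AT-rich non-repetitive
padding. Sequences are i.i.d. multinomial draws at the target frequencies;
N-strand genes are placed as reverse complements of a draw whose reverse
complement meets the J-strand target, so J-strand counts match in
expectation. Protein-coding genes receive ATN starts and complete (TAA) or
incomplete (T/TA) stops on their coding strand so codon-level bookkeeping
is exercisable. Rearrangement histories are explicit event lists
(inversion, translocation ± inversion, TDRL with explicit or seeded random
loss mask, strand flip, control-region relocation) applied to a ground
pattern, with a before/after log.

One integer seed drives a spec; components draw from sub-streams at fixed
seed offsets, so adding a component never perturbs another's draws, and
emission is byte-identical for identical spec and seed. The flank bases
abutting a generated repeat array are forced to break the array's period
(three positions deep), which is what "non-repetitive flank" must mean for
boundary questions to have well-defined answers.

What the generator does **not** emulate: substitution models beyond
i.i.d. draws (no codon structure beyond termini, no rate heterogeneity),
indels, within-unit repeat indels, secondary-structure-driven composition,
heteroplasmic copy-number mixtures, or evolution along trees. Passing
recovery tests on this generator therefore demonstrates correctness of the
implementations under clean conditions, not robustness to everything real
control regions do; the repeat detector in particular is documented as
indel-intolerant.

## Test conditions and problem sizes

The suite runs the fixture analyses exactly; property tests use fixed
seeds throughout. Chosen sizes: the TDRL oracle covers all permutations of
n ≤ 7 against 2^n enumeration; the repeat detector is measured over 200
seeded trials spanning periods 5–60 nt, 2–20 copies and substitution rates
up to 0.05 per site (recovery of period and copy number ± 0.1 must be
≥ 95%; at rates near 0.05 with edge substitutions the true boundary is
genuinely ambiguous at sub-copy resolution, which the margin absorbs);
cloverleaf arm recovery over 200 seeded tRNAs spanning full, T-less and
D-less configurations with up to one mutated stem pair (≥ 95%); skew
recovery on emitted genomes within 3/√L of the target; and 25-trial sweeps
per event class for rearrangement identification (inversions and
translocations must be identified every time, TDRL-generated orders must
always test feasible). These sizes give stable pass/fail behavior at
desk-scale runtimes.

## Known limitations

* Origin-spanning features are rejected rather than split.
* The repeat detector has no indel model and reports arrays at exact
  period only.
* The cloverleaf fitter's windows encode metazoan mitochondrial tRNA
  anatomy; exotic architectures outside 50–75 nt are out of range by
  design.
* The survey module is the instrument, not the dataset: genome-census
  ratios depend on what a database contained at a date, and the package
  makes no attempt to ship or reconstruct such a census.
* GenBank parsing is a minimal subset (LOCUS, CDS/tRNA/rRNA with plain or
  `complement()` locations, `/gene`, `/product`, ORIGIN); `join()` across
  the origin is rejected, and unmappable product names are skipped with a
  warning.
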