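---
title: "Methods: hierarchical sequence-family reduction in mulsel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hierarchical sequence-family reduction in mulsel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mulsel)
```

## The problem and the model

Database searches over modern sequence collections return raw hit lists far
too large to align directly, and a representative subset is needed both to
remove bias towards over-sequenced subfamilies and to make visual assessment
possible. `mulsel` reduces such a list by *hierarchical condensation*: cheap
alignment-free ordering brings similar sequences close, small local multiple
alignments ("mini-alignments") form among order-adjacent sequences above a
similarity cutoff, one representative per mini-alignment survives to the
next round, and the cutoff falls from stage to stage. The design assumption
is that order only needs to be roughly right: a missed pair is brought
together at a later, more permissive stage, and an occasional surviving
duplicate is harmless.

Throughout, a *family* is operationally a group of sequences alignable among
themselves at a given cutoff but not with any other group at that cutoff;
a *subfamily* is the same notion under a stricter cutoff. No evolutionary
claim is attached.

## Peptide presort

Each sequence is reduced to its set of distinct overlapping k-peptides.
Peptides are hashed base-25 over the residue codes and inserted once into an
unbalanced binary search tree; in-order traversal emits the sorted list in
O(L log L). Because the tree stores only observed peptides, k is not limited
by alphabet size. Two sequences are scored by their count of common peptides
in one two-pointer pass over the sorted lists.

Parameters (with defaults):

* `k = 4` (tetra-peptides). Lengths 3–7 behave similarly on benchmark data,
  with 5–6 marginally better and 4 a good compromise between sensitivity and
  specificity; nucleotide data, with its small alphabet, wants the longer
  end.
* `M = 3` retained top partners per sequence and `min_score = 10`: storage
  is O(N·M) and weak, mostly spurious pairs are never kept. Saving only the
  top hit loses little; the defaults are kept for safety.
* `adjacency_bonus = 2`: search output is seldom in random order, so pairs
  adjacent in the input get a small bonus that preserves pre-existing order
  when no stronger signal exists. The value is deliberately below
  `min_score`, so adjacency alone can never store a pair with no real
  similarity.
* `n_blocks`: at the earliest (cheapest, most redundant) stages the pair
  evaluation is restricted to contiguous blocks of the current order and
  repeated over several passes. Blocks are slices of the *current* order, so
  each pass mixes what previous passes separated.
* `soften` 0–4: optional many-to-one alphabet reduction before peptide
  extraction. The groupings are this package's own, nested so that
  coarsening is monotone: level 1 merges {I,L,V}, {K,R}, {D,E}, {S,T},
  {F,Y}; level 2 adds {N,Q} and widens to {F,W,Y}; level 3 adds {A,G} and
  {H,K,R}; level 4 keeps six classes ({A,G,I,L,M,V}, {F,W,Y}, {H,K,R},
  {D,E}, {N,Q,S,T}, {C,P}). On the artificial benchmark softening does not
  help — its mutation model is blind to residue similarity — and the default
  is 0.

The stored pairs, taken in descending score order, grow clusters by single
linkage in one pass; clusters are laid out contiguously (accretion order
inside, best-scoring cluster first), and pairless sequences keep their
relative order at the end. Ties everywhere break towards the smaller
sequence index, so the presort is fully deterministic.

## The condensation engine

Units (sequences, later mini-alignments) within `span = 50` of each other in
the current order are compared by global profile/profile dynamic
programming. A column pair scores the mean of `matrix[a, b]` over all member
cross-pairs, gaps scoring zero, and the reported similarity is

> 100 × (sum of column scores on the optimal path) / (length of the shorter
> profile),

so that under the identity matrix two identical sequences score 100 and a
half-identical pair scores 50 — the anchor that makes cutoffs interpretable
as percent identity. Pairs at or above the stage cutoff are single-linkage
clustered and merged progressively in descending pair-score order; each unit
joins at most one merge per cycle, and a stage runs `n_iterations = 3`
cycles, bounding mini-alignments at 2³ = 8 members.

Numerical conventions, fixed here because the score normalisation admits
several readings:

* **Normalisation by the shorter profile.** Dividing by aligned length
  would let long gaps dilute the score; shorter-length normalisation keeps a
  fragment's similarity to its parent high, which the length penalty (not
  the aligner) is responsible for punishing. Configurable in principle but
  baked into the anchor above.
* **Gap penalties on the score scale.** `gap_open = 10`, `gap_extend = 1`
  are points on the final 0–100 scale (raw dynamic-programming costs scale
  with the shorter profile length). At these values a gap must recover on
  the order of ten matched columns to pay for itself, which stops the
  aligner from "shredding" two compositionally similar but unrelated
  sequences into spurious matches — the property the reversed-doppleganger
  control tests.
* **Free terminal gaps.** Length differences between family members are
  dominated by terminal truncation; charging for them would conflate the
  aligner's job with the selector's.
* **Banding.** At cutoffs above 60 the DP is banded to ±`max_insert = 10`
  columns around the length-corrected diagonal: near-identical sequences
  need only small inserts, and the band makes the expensive early stages
  linear-width. The band is dropped at cutoffs ≤ 60.
* **Ties.** Equal DP states resolve match > gap-in-B > gap-in-A; equal pair
  scores rank by smaller first index. Identical inputs therefore give
  byte-identical outputs.
* **Degenerate inputs.** Sequences shorter than k contribute an empty
  peptide list and score 0 against everything in the presort, but are never
  dropped: they ride through to the final alignment. Empty profiles are an
  error.

## Representative selection

Within a mini-alignment each member's penalty is the sum of a
length-deviation term `p = ln(d² + 1)` — about 5 at a deviation of 12
residues, about 9 at 100 — and its annotation biases (PDB −60, UniProt −20,
"mutant" +40, "fragment" +50, "probable" +1, "precursor" +2,
"uncharacterised" +5, "hypothetical" +5). The target length is the mean
member length, or the SEED sequence's length when one is present, in which
case members *longer* than the seed pay only half the length penalty — a
deliberate asymmetry against the progressive loss of termini over repeated
search-and-select rounds. A SEED (upper-case, anywhere in the header) takes
−100 and therefore always survives; members of a seed alignment (lower-case
`seed`, in the identifier only, because titles often contain the English
word) take −50. The units clash — a natural logarithm against integer
keyword biases — but the biases act within a mini-alignment whose members
are already similar in length, where the length term is small; the sums are
taken as raw numbers. Ties break towards the larger represented count, then
the smaller input index. The survivor's `n_represented` becomes the sum over
members, so the total represented count is conserved through the whole run
(an invariant the test suite checks end-to-end).

## The staged schedule and final alignment

The default plan lowers the cutoff 90/80/70/60/50 with presort passes and
blocks 8/4/2/1/1: early stages only unite near-duplicates, so they can
afford narrow bands, small spans and blocked presorts; later stages see far
fewer sequences and can pay for exhaustive pair evaluation. After the last
stage the floor cutoff repeats (at most 10 cycles) until a cycle removes
nothing or the collection reaches `stop_at`.

The final multiple alignment computes all pairwise *sequence* similarities
among the survivors, joins pairs at or above the floor by single linkage,
and merges the clusters progressively in rank order. Clustering on sequence
rather than merged-profile scores matters: averaging a diverse family's
profile dilutes its column scores, and requiring merged profiles to clear
the floor splits exactly the families one wants whole. The default floor of
25 was calibrated on generated benchmark data by measuring the two score
distributions it must separate: survivor pairs from the same family span
roughly 20–58 under the identity matrix while cross-family pairs stay below
about 17, so 25 sits in the gap with margin on the dangerous (cross-family)
side. Batched operation (`run_batched`) reduces independent batches to the
70 % level — batches share no state, so they parallelise trivially — then
combines and continues at the lower cutoffs.

## The artificial benchmark

`make_families()` grows 20 families from homopolymers of each amino acid by
uniform random single-position substitution over the 26 letters, with the
non-amino-acid codes B, J, O, U, X, Z becoming gap characters (stripped at
the end, which is why emitted sequences are shorter than the 100-residue
seed). Whenever the starting residue falls to one third of the (gap-free)
sequence or below, random positions revert to it until it is again above one
third: one third is close to the limit at which similarity is detectable at
all, so members of one family can always be aligned with each other and
never with another family. Snapshots are taken at geometrically spaced
points along a 250-event trajectory, so each family spans near-identical
pairs down to fully saturated ones; sequences are then shuffled by a random
number. Defaults (length 100, 250 events, equal family sizes) are fixed
study conditions, not tuning knobs.

What the generator emulates: graded divergence within families, a hard
compositional floor separating families, shuffled input order, and length
variation from the gap-stripping. What it does not emulate: substitution
preferences between similar residues (mutations are uniform), insertions
with positional structure, domain architecture, or annotation noise.
Passing the 20-family endpoint therefore demonstrates the sorting,
condensation and selection machinery — not performance on real homology
detection, where an exchange matrix (`blosum_matrix()`) and external
judgement are needed.

`make_dopplegangers()` adds each sequence's reversal (`_rev`): same length,
same composition, locally similar statistics, yet not validly alignable —
a hard negative control. `make_markov_family()` supplies native-like
sequences (an order-2 Markov ancestor plus a substitution trajectory) when
no real family is at hand; with reversals it exercises the segregation
harness (`segregation_score()`), which reports label purity, switch counts
and survivors per label along the final order.

## Visualisation

Alignments render as stacked panels: per-residue colours (physico-chemical
for proteins, the usual G/A/C/T colours for nucleotides), optional state
tracks (α-helix red, β-strand green; transmembrane segments add a blue
component over the helix red, giving the purple that marks TM helices; RNA
stems green descending, red ascending), and column-averaged "reflections" of
both, in which conserved columns appear as saturated bands because the mean
of identical colours is the colour itself. Gap cells are white and excluded
from the means. The exact hues are package conventions, exposed in
`colour_scheme()` and freely overridable; output is plain SVG text so a
given input yields a byte-identical file. Predictors that produce the tracks
(secondary structure, TM topology, RNA folding) are consumed as plain-text
state strings, never run.

## Problem sizes and determinism

The test suite validates the operations against independent oracles
(brute-force set intersection, naive single linkage, a plain-R affine-gap
DP) and runs the full benchmark at 2,000 sequences — 100 per family, enough
for every family to be chain-connected across its divergence range — in
roughly a quarter of a minute; the acceptance script reruns it from scratch
at the same size. Pipeline and generator are deterministic given the
generator seed; the pipeline itself contains no randomness.

## Known limitations

* Presort scores saturate for repeat-rich sequences (distinct-peptide sets
  collapse), so homopolymer-like sequences score at most 1 against anything
  and rely on the alignment stages to be placed.
* Profile columns are unweighted by represented counts; a representative
  standing for thousands counts the same as a singleton when profiles merge.
* The identity anchor makes cutoffs interpretable, but with an exchange
  matrix (real proteins) the score is no longer percent identity and
  cutoffs need loosening, exactly as when moving from artificial to real
  data.
* Very large inputs (beyond ~10⁵) should be processed in batches; the
  pair-evaluation time of the alignment stages remains quadratic in the
  survivors per stage.
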