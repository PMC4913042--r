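---
title: "Stack/tail scoring of structural-variant junctions: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stack/tail scoring of structural-variant junctions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(stacktail)
```

## The model

A structural variant creates a novel adjacency between two reference loci.
Reads sequenced across that adjacency cannot align contiguously to the
reference: an aligner soft-clips them, leaving an aligned *stack* portion and
a clipped *tail*. Two observations drive the method:

* the stack ends of junction-spanning reads share a coordinate — the
  breakpoint — so recurrent clip coordinates are breakpoint candidates;
* if the hypothesized junction sequence is correct, the *whole* read,
  stack plus tail, realigns contiguously to it, and the depth of that
  realignment across the junction point is direct evidence.

Given a candidate junction $C$ (two oriented reference flanks concatenated at
candidate breakpoints), every stacked read $i$ is locally realigned to $C$ and
contributes

$$S(C) = \sum_{i=1}^{n} Q_i \, \min\{l_{A,i},\, l_{B,i}\}$$

where $l_{A,i}$ and $l_{B,i}$ count the read's aligned bases on the two sides
of the junction point and $Q_i \in [0,1]$ is its alignment quality. The
$\min$ is the essential term: a read aligned entirely on one side — including
every read supporting only a "half-correct" junction whose partner flank is
wrong — has $\min = 0$ and contributes nothing, while a read centred on the
junction contributes up to half its length. Support therefore grows with both
the number of spanning reads and how deeply they span, and false junctions
assembled from unrelated flanks score near zero without any explicit negative
model.

### Alignment quality

The realignment literature leaves the exact form of the per-read quality
open (mapping quality, aligner score, or a base-quality composite are all
defensible). This package defines

$$Q_i = \frac{\text{local alignment score}_i}{\text{match score} \times \text{read length}}
\quad \text{clipped to } [0, 1],$$

so a perfect full-length alignment has $Q_i = 1$ and its contribution is
exactly its spanning overlap in bases. The definition is dimensionless,
monotone in alignment agreement, and keeps $\log_{10} S$ on the scale of
(reads × bases): tens of spanning reads of a few hundred bases give
$\log_{10} S \approx 3$, which is where the trained decision threshold
(below) sits. Per-base Phred qualities enter only through tail trimming, not
through $Q$; a base-quality-weighted $Q$ would be a natural extension.

### Realignment

Realignment is Smith–Waterman local alignment (via Biostrings), both strands,
defaults match $+1$, mismatch $-3$, and affine gaps costing
$\text{open} + L \times \text{extend} = 5 + 2L$ for a gap of length $L$ (the
Biostrings convention; a one-base gap costs 7). Alignments scoring below
`min_align_score = 20` — roughly, fewer than 20 clean matched bases — are
discarded as noise. Strand ties go to `+`; traceback ties follow the
aligner's deterministic preference. A test-suite oracle (an independent
three-state dynamic program) verifies optimal scores for short reads against
short junctions. Each physical read is realigned once per junction even when
clipped at both ends, and by default contributes to every junction it aligns
to, since $S$ is defined per junction; a winner-takes-all mode assigns each
read only to its best junction.

## Coordinates and junction geometry

All coordinates are 1-based inclusive, the R/Bioconductor idiom, in both the
API and the outputs; BED/BEDPE readers and writers convert at the boundary.
A breakpoint is the coordinate of the flank base adjacent to the junction:
for a flank that ends at the junction (a right-side clip) the last aligned
base, for a flank that begins there (left-side clip) the first aligned base.

A junction spec is `(chromA, posA, orientA | chromB, posB, orientB)`: flank A
is the `flank_len` reference bases ending at `posA` (reverse-complemented and
taken from `posA` rightward when `orientA = "rc"`), flank B mirrors it. The
spec and its mirror `(B, flip(orientB) | A, flip(orientA))` describe the same
adjacency — the built sequences are reverse complements — so specs are
canonicalized to the representation whose `(chrom, pos)` sorts first. The SV
class is read off the geometry: different chromosomes → interchromosomal
translocation; same chromosome, equal orientations → deletion or
tandem-duplication (insertion-like) depending on breakpoint order; mixed
orientations → inversion edge. No separate "intra-chromosomal translocation"
class is assigned: without an arbitrary distance cutoff it is geometrically
indistinguishable from a long deletion/duplication, and the collapse and
comparison machinery treats classes only as merge keys. Clip-side
compatibility follows from the same picture: a forward A flank needs right
clips, a forward B flank needs left clips, and `rc` flips the side — which is
why an inversion search pairs right clips with right clips.

`flank_len` defaults to the longest observed read plus 50 bases, so every
junction-spanning read can align entirely within the candidate sequence.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `min_tail` | 10 bases | shortest soft-clip tail kept as evidence; shorter tails realign ambiguously |
| `min_base_quality` | 3 (Phred) | tail bases below this at the tail's far end are trimmed before the length filter |
| `min_stack_reads` | 2 | weakest reading of a "recurrent" clip coordinate |
| `fuzz` | 0 bases | clip-clustering slack; 0 suits error-free/targeted data, ~2 absorbs aligner jitter in real data |
| `scheme` | +1/−3, gap 5+2L, floor 20 | realignment scoring |
| `threshold` | trained | decision level on log₁₀(S); the comparison is closed (a score exactly at threshold passes) |
| `collapse_window` | 500 bases | single-linkage window for merging similar calls |
| `comparison_window` | 500 bases | per-breakpoint window for call-set comparison |
| `coverage_k` | 10 | whole-genome mode drops junctions whose ±500-base mean depth exceeds k × the genome median |

Threshold training takes labeled `(log10_S, is_true)` scores and returns the
midpoint between the lowest-scoring true positive $t$ and the highest false
positive strictly below it, or $t/2$ when no false positive lies below — by
construction strictly below every true positive, so the training set is
recovered with full sensitivity. Training, thresholding and plotting all work
on the $\log_{10}$ scale, where the support distributions of true and false
junctions separate cleanly.

## Whole-genome mode

Scoring every pairwise combination of genome-wide clip candidates is
combinatorially hopeless, so whole-genome calling narrows the space first:

1. candidate breakpoint *pairs* come from an external BEDPE (e.g. a
   paired-end caller's output) or from clusters of ≥2 discordant read pairs;
2. flank orientations, when absent, are voted from discordant pairs within
   1 kb: an FR-like strand combination maps to a forward/forward join, FF/RR
   to one reverse-complemented flank; ties or zero votes expand the spec to
   all four orientation pairs rather than guessing — scoring is cheap at
   candidate scale and wrong orientations score near zero;
3. interval midpoints are refined to the strongest compatible local stack
   within ±500 bases (specs with no stack keep the midpoint, flagged
   low-confidence);
4. junctions whose breakpoints sit in excessive-coverage regions (mean depth
   over ±500 bases above `coverage_k` × the genome median) are excluded as
   repeat artifacts; and
5. scores are adjusted linearly for residual local coverage,
   $S_{\mathrm{adj}} = S \cdot \mathrm{baseline} / \max(\mathrm{local},
   \mathrm{baseline})$ — scaling pile-ups down, never weighting thin regions
   up. The raw $S$ is always retained alongside and the adjustment form is
   recorded in the call-set configuration so results are auditable.

## The simulator, and what passing tests do (and do not) show

The simulator generates i.i.d. uniform ACGT chromosomes, rewrites them
through an explicit donor-to-reference segment map for each planted SV
(translocation, optionally reciprocal; deletion; tandem duplication;
inversion with both edge junctions), samples uniform reads on both strands
with substitution errors at a configured rate, and emits truth alignments by
mapping each read's donor interval back through the segment map — reads
crossing a junction get their longer side aligned and the shorter side
soft-clipped, exactly the structure a real aligner would produce. One RNG
substream per purpose (genome, positions, errors) keeps read placement fixed
when the error rate changes, and everything is byte-deterministic given the
seed. Reads crossing two junctions are assigned to their longest segment and
flagged.

The substitution-only error model is deliberate: substitutions perturb $Q$
and alignment scores — the quantities the statistic is sensitive to — while
leaving true clip boundaries intact, so planted breakpoints remain exact
under errors. What the simulator does *not* emulate: platform-specific error
structure (homopolymer indels, quality decay), alignment ambiguity in
repetitive sequence (the truth aligner always clips at the exact junction,
where a real aligner in a repeat may absorb the tail as mismatches — a known
failure mode that suppresses the clip signal entirely), chimeric library
artifacts, and GC-coverage bias. Passing the replica therefore demonstrates
the correctness of the machinery — stack detection, junction construction,
scoring, thresholding, collapsing — under clean mappable conditions, not the
caller's operating characteristics on real tumor genomes.

### The replica study design

The targeted evaluation is replicated at desk scale: 8 captured regions
scaled to 10-kb synthetic chromosomes; 23 test samples, each carrying one
translocation of a cycling canonical type (t(1;19), t(4;11), t(9;22),
t(12;21)), the first 8 reciprocal — 31 planted junctions, 153 unrearranged
region instances; single-end 250-base reads at 30× with error rate 0 (the
clean setting; read length and coverage are fixed design choices
representative of long-read targeted capture chemistry). The
threshold is trained on an independent 4-sample / 7-junction design simulated
under a shifted seed. With clean reads, false junctions score exactly zero,
so training exercises the $t/2$ fallback and lands near $\log_{10} S \approx
1.6$; the true-junction scores concentrate near 3.2, comfortably above it.
Evaluation reports junction-level sensitivity/PPV (windowed and exact) and
the sample-level type call — the type of each sample's highest-scoring passed
call, reflecting the design position that ranking, not just thresholding,
carries the per-sample decision.

## Numerical and degenerate-input choices

* Clip clustering is greedy-modal: the modal position (ties to the smaller
  coordinate) absorbs clips within `fuzz`; with `fuzz = 0` this is an exact
  group-by. Deterministic, order-independent output.
* The candidate density filter removes the weakest candidate (ties dropped
  from the larger coordinate) from the leftmost over-full 1-kb window until
  all windows comply — deterministic survivor sets.
* Collapsing is single-linkage over calls sharing chromosome pair, class and
  orientation pair, both breakpoints within the window; the top-scoring
  member (ties to smallest coordinates) represents the cluster and keeps its
  own score. Idempotent; reciprocal derivatives never merge because their
  orientation pairs differ.
* Call-set comparison matches greedily on total breakpoint distance,
  one-to-one, making the intersection count symmetric.
* Degenerate self-pairs (one candidate paired with itself in an inversion
  search), junctions whose flank falls entirely outside a chromosome, and
  empty candidate sides all drop out with warnings rather than errors; an
  empty region yields an empty call table, not a failure.
* Hard-clipped read ends carry no bases and are never used as tails.

## Known limitations

* Novel insertions approaching or exceeding the read length cannot be
  represented as two-flank reference junctions and are out of scope.
* Repetitive breakpoint regions defeat the clip signal at its source (reads
  align with mismatches instead of soft-clips); the coverage exclusion
  removes the worst regions rather than rescuing them.
* Scoring is quadratic in candidates × reads near them; whole-genome use
  depends on the candidate-pair narrowing described above.
* Germline/somatic status, genotype likelihoods, and recursive detection of
  complex multi-breakpoint events are not modelled.
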