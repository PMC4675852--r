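---
title: "Mining tetraspanin gene families: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining tetraspanin gene families: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tetmine)
```

This vignette documents the models and procedures `tetmine` implements,
the parameters that matter, what the synthetic-data generators emulate
(and what they deliberately do not), and the numerical and design choices
made where the problem left them open.

## The identification model

A canonical plant tetraspanin is a 4-pass membrane protein with both
termini cytoplasmic: Ntail–TM1–EC1–TM2–ICL–TM3–EC2–TM4–Ctail. The region
model is derived purely from the TM segment list and the sidedness of the
N-terminus, by alternation: crossing a TM helix flips the membrane side.
Consequences the implementation embraces:

* With the N-terminus inside, the TM1–TM2 and TM3–TM4 loops are
  extracellular; EC1 and EC2 are those loops by definition, and the small
  TM2–TM3 loop is the ICL.
* With the N-terminus outside, only one loop is extracellular. That loop
  receives the EC1 label, EC2 is undefined, and `orientation_ok` is
  `FALSE`. Rules that need EC2 are then *not evaluable* rather than
  failed: a protein is only accepted when every enabled rule is both
  evaluable and passed, and a rejected protein's failed-rule list names
  only rules whose inputs were defined. This keeps per-rule diagnostics
  sharp (a 3-TM protein fails "four_tm", not half the cascade).
* Proteins with unknown sidedness are scored under both orientations and
  the more favourable verdict kept, flagged `side_assumed`.

### Rule cascade parameters

| rule | default | notes |
|------|---------|-------|
| TM count | exactly 4 | the defining feature |
| EC2 > EC1 | — | loop sizes must be unequal in the canonical direction |
| EC2 cysteines | ≥ 9 | `strict_cys` switches to exactly 9; "at least" is the default because a count rule on a variable loop is brittle under annotation noise |
| signature | `GCC[KR]P` core | the longer `SGCC[KR]PP` is reported when present and required in `signature_mode = "strict"`; the core is the screening form because the long form is an observation about families already found, not a defining criterion, and both K and R variants are accepted throughout |
| tail length | ≤ 60 aa | "short tails" has no standard number; 60 admits every member of known plant families (longest family proteins ≈ 380 aa) while excluding receptor-like proteins with large cytoplasmic domains |
| orientation | required | loops 1 and 3 extracellular |

The one-cysteine-in-EC1 regularity is reported (`ec1_cys`) but not used as
a filter: it is a family-level observation, not an identification
criterion. N-glycosylation sequons (`N-{P}-[S/T]` in EC2, overlapping
occurrences included) and juxtamembrane cysteines (within 5 residues of a
TM boundary on the cytoplasmic side, candidate palmitoylation sites) are
sequence heuristics, clearly distinct from trained predictors, and are
likewise report-only.

### Hydropathy TM prediction

`predict_tm_hydropathy()` is a self-contained fallback when no external
topology prediction is available: per-residue Kyte–Doolittle values are
averaged over a centered 19-residue window (window average > 1.6 seeds a
segment), segment boundaries extend outward over contiguous residues with
positive hydropathy, segments closer than 3 residues merge, and segments
shorter than 8 residues are dropped. Sidedness uses the positive-inside
rule: the orientation placing more K/R in non-membrane segments wins, ties
resolving to inside. The window/threshold pair is the classic
Kyte–Doolittle setting for membrane-spanning detection; boundary extension
corrects the systematic erosion a fixed-window threshold produces at helix
ends.

## Conservation, identity, phylogeny

Pairwise global alignment uses affine gap penalties (open 10, extend 0.5)
and BLOSUM62, delegated to `Biostrings::pairwiseAlignment()`. Unknown
residue letters are scored 0 with a warning rather than erroring, so
slightly dirty proteomes still align.

Percent identity counts columns with identical non-gap residues;
similarity adds columns whose pair scores positively under the matrix.
Because online identity/similarity tools offer several denominators and
published percentages rarely state which was used, all three are exposed —
`alignment_length` (default), `shorter_seq`, `mean_length` — and clean-room
reproduction of any specific tool's numbers should be expected only to a
couple of percentage points.

The progressive aligner builds a guide tree by neighbor joining on
pairwise p-distances, then merges profiles bottom-up with sum-of-pairs
scoring over column frequency vectors; merge order and DP tie-breaking
(diagonal, then up, then left) are deterministic, so identical inputs give
identical columns. No installed R package provides progressive protein
MSA, so the merge step is implemented here; it is intended for
family-scale inputs (tens of sequences), not genome-scale alignment.

`nj_tree()` implements Saitou–Nei agglomeration directly because the
surrounding contracts are specific: ties in the Q-criterion break by
lexicographic pair order, and negative branch-length estimates are clamped
to zero with the deficit moved to the sibling edge so path lengths are
preserved. `ape`'s independent NJ implementation serves as a cross-check
in the test suite (both reproduce random additive matrices to < 1e-9),
never as the implementation. Bootstrap support resamples alignment columns
with replacement, rebuilds the tree from p-distances (pairwise gap
deletion) per replicate, and counts bipartitions; a fixed seed makes
supports exactly reproducible. Distances for tree building are
p-distances: for within-family divergences (tens of percent) model
corrections change little and add failure modes.

## Gene architecture

Intron phase is the cumulative CDS length 5′ of the intron modulo 3,
computed strand-aware from the CDS intervals only. Introns lying entirely
in untranslated regions get an undefined phase and are excluded from the
phase census but included in length statistics — a phase is a property of
a reading frame, and UTR introns have none. `protein_position` is
`floor(cum/3) + 1`, the codon the intron interrupts or follows, which is
what `map_intron_to_domain()` looks up in the region model.

Tandem duplication follows the standard criterion: same chromosome, at
most 10 intervening unrelated genes, implemented inclusively (exactly 10
intervening still counts; a flag changes the boundary). Intergenic
distance is the count of bases strictly between gene extents under 1-based
inclusive coordinates (genes at [100,200] and [300,400] are 99 bp apart),
so the number is well-defined when checked against annotation-derived
gaps.

Segmental duplication is a simplified colinearity chainer, not a
reimplementation of a synteny database pipeline: anchors (homologous gene
pairs) chain when consecutive pairs are within 500 kb on both chromosomes
with consistent relative order (both orientations tried), and chains of ≥ 3
anchors form blocks. An anchor is "in a block" when some valid chain of
qualifying length passes through it, computed exactly by forward/backward
longest-chain DP; the test suite checks this against exhaustive
enumeration on small anchor sets. Pre-computed block tables can be used
instead by building the anchor data frame from them.

## Promoters

Windows anchor at the **translation** start (the first CDS base), not the
transcription start: 1000 bp upstream, truncated and flagged at contig
edges. Scanning expands IUPAC codes exactly, reports every occurrence
including overlaps on both strands (minus-strand hits are occurrences of
the reverse complement, with offsets still on the window's own 5′→3′
axis), and orders hits deterministically. A leftmost-greedy non-overlap
mode exists for counting discrete sites. The bundled dictionary holds one
canonical PLACE-style consensus per element class (ABRE `ACGTG`, HSE
`AGAANNTTCT`, LTR `CCGAC`, MeJA `CGTCA`/`TGACG`, root `ATATT`,
POLLEN1LELAT52 `AGAAA`); it ships as an editable TSV because element
classes, not exact strings, are the stable concept — users matching a
specific database's counts should export that database's patterns.

## Expression

`ddct()` is pure Livak: amplification efficiency fixed at 2, technical
replicates averaged before anything else, ΔCq per biological replicate,
ΔΔCq against the mean control ΔCq, log2 fold change = −ΔΔCq, cell = mean ±
SE over biological replicates. Any Cq shift shared between a target and
the reference gene within a replicate cancels exactly (tested as an
invariance).

Two standard errors are reported, and the distinction matters:

* `se` — SE of the biological replicates' spread (`sd/√n`), the error bar
  convention for expression figures;
* `recovery_se` — SE of the *estimate*, `√(var(ΔCq_cond)/n +
  var(ΔCq_ctrl)/n)`. The control-mean term is shared by every replicate of
  a treated condition, so it does not appear in the within-condition
  spread; comparing an estimate against a known truth with `se` alone
  systematically understates the uncertainty (with 3 replicates, the
  nominal "±3 SE" captures only ~85% of estimates, while ±3 `recovery_se`
  captures ~97%). Simulation-recovery checks in this package therefore use
  `recovery_se`.

The regulation threshold is |log2FC| ≥ 2 by default — a literal reading of
"2-fold change on a log2 scale", i.e. 4-fold linear. The phrase is
genuinely ambiguous in the literature, so `tau` is a parameter; the
boundary is inclusive. Hierarchical clustering exposes Euclidean or
correlation distance with average or complete linkage (none of these is
canonical for expression heatmaps; defaults are Euclidean/average), rows
are pre-sorted by gene id so leaf order is deterministic under ties, and
missing cells are imputed as 0 for clustering with the mask returned for
rendering.

## The synthetic-data generators

The generators define the conditions under which the pipeline is
validated; their defaults are fixed, not tuning knobs.

* `make_proteome()` — 15 tetraspanins among 500 decoys (125 per class).
  Tetraspanins satisfy every rule by construction: four 22-residue TM
  helices drawn from strongly hydrophobic residues, EC1 ≈ 15 aa with one
  cysteine, EC2 ≈ 90 aa with nine cysteines and an embedded
  `SGCC(K/R)PP`, basic cytoplasmic segments, tails ≤ 40 aa. Each decoy
  class violates exactly its designated rule (3/5 helices; no GCC core;
  EC2 of 18 aa under a 25-aa EC1 with signature and cysteines intact; an
  80-aa N-tail), so per-rule specificity is measurable. Loop backbones
  exclude C, G, K and R so cysteine counts, signatures and the
  positive-inside heuristic are controlled exactly; TM flanks are
  hydrophilic so the hydropathy predictor's boundaries are sharp.
* `make_annotation()` — fifteen gene models on both strands mirroring a
  small plant family: mostly two-exon genes, two intronless, one
  four-intron gene realizing the phase multiset {0,0,1,2} (exon lengths
  99, 99, 100, 100, …), one ten-intron gene; intron lengths span 95–4200 bp
  with the extremes planted deterministically. Promoters are motif-free
  pyrimidine backgrounds (no A/G kills every forward consensus; forbidding
  TTT runs kills the only pyrimidine-only reverse complement) with motifs
  planted at recorded offsets; ground-truth counts are recomputed with a
  plain-regex IUPAC counter, independent of the Biostrings-based scanner
  it validates, because dyad-symmetric consensi (HSE) and mutual reverse
  complements (the MeJA pair) make both-strand counts exceed planted
  counts by design. Position tables realize a 7530-bp adjacent pair, a
  10-intervening-gene pair (tandem boundary) and an 11-gene pair (beyond
  it); anchor tables hold one clean 5-anchor block and one chain broken by
  a 600-kb gap.
* `make_cq()` — Cq = gene baseline + per-(condition, replicate) loading
  shift (shared with the reference gene) − true log2FC + N(0, 0.1), 3
  biological × 2 technical replicates, reference gene noise-only around
  its baseline. True fold changes are uniform on [−4, 4] unless supplied.

What the generators do **not** emulate: realistic codon usage, GC
structure or repeats; homology between family members beyond what the
shared construction alphabet induces (so synthetic identity percentages
are not calibrated to any real family's values); UTR structure in the
gene models (all exons fully coding, UTR introns are tested with
hand-built fixtures); amplification-efficiency variation in qPCR. Passing
tests therefore demonstrate algorithmic correctness against controlled
truth, not performance on real annotation noise.

## Problem sizes and determinism

The validation suite runs 20 proteome seeds (515 proteins each), 100
random additive matrices up to 8 taxa, 300-replicate bootstraps over 10
seeds on 4-taxon alignments of 200 columns, 200 random gene models for the
phase oracle, and 20 noisy Cq tables — sizes chosen so the full pipeline
is exercised end-to-end in about a minute while keeping every Monte Carlo
rate estimate stable to a couple of percent. A single integer seed drives
every generator; per-artifact streams are derived by fixed offsets, and
identical seeds give byte-identical outputs.

## Known limitations

* The hydropathy predictor is a windowed heuristic; re-entrant loops,
  marginally hydrophobic helices and signal peptides will confuse it, as
  they do any hydropathy-only method. Import real predictor output when
  available.
* The progressive aligner has no iterative refinement; deep or highly
  gappy families deserve a dedicated MSA tool, and alignments can be
  supplied externally through `alignment()`.
* The colinearity chainer sees only the anchors it is given; it does not
  discover homologous pairs.
* `ddct()` assumes perfect doubling per cycle; efficiency-corrected
  variants are out of scope.
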