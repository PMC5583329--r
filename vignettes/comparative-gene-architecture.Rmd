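---
title: "Comparative gene architecture, intron evolution and microsynteny with introscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative gene architecture, intron evolution and microsynteny with introscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(introscape)
```

## The analysis this package implements

Gene families such as the collagen-chaperone serpin HSP47/SERPINH1 are
studied through three largely independent kinds of evidence:

1. **Gene architecture.** Spliceosomal intron positions are rare, nearly
   irreversible genetic markers. When each intron is expressed in the codon
   numbering of a fixed reference protein (mature human
   alpha-1-antitrypsin for serpins) together with a phase letter, positions
   become comparable across genes and species: the ancestral serpin pattern
   is four exons and three introns at 192a, 225a and 300c, and
   lineage-restricted gains (e.g. 36b and 102b in the first exon of one
   fish paralog) stand out immediately.
2. **Microsynteny.** The ordered list of flanking genes around a focal gene
   distinguishes orthologous loci from duplicated ones and lets an
   ancestral locus be anchored by conserved markers (e.g. a P2RY6-class
   receptor adjacent to the focal gene).
3. **Sequence features.** Percent identity, per-column conservation,
   reactive-center-loop (RCL) composition and the C-terminal ER-retention
   tetrapeptide ([RKH]DEL) classify family members functionally.

`introscape` implements all three, plus the event-inference layer that ties
them to a time-calibrated species tree (Dollo parsimony for intron
gain/loss, species-overlap duplication detection, branch-interval dating),
and a scripted gene-family simulator so that the entire pipeline can be
validated against a known truth without any external downloads.

## Intron numbering and the phase convention

An intron interrupting a CDS after `c` coding nucleotides falls in codon
`q = ceiling(c/3)` with remainder `r = c - 3(q-1)` in {1,2,3}. The package
fixes the letter convention as `a` = after the first nucleotide of codon
`q`, `b` = after the second, `c` = after the third (i.e. between codons `q`
and `q+1`). This is the only assignment family consistent with the
conserved serpin exon sizes: introns 192a and 225a bound a 99 bp exon, and
99 is a multiple of 3 exactly as same-letter phase arithmetic requires
(`(c2 - c1) mod 3 == (r2 - r1) mod 3`). The same arithmetic settles
ambiguous renderings of individual labels: a gain at coding offset 107 has
remainder 2 and is therefore `36b`, never `36c`.

Gene codons are projected onto reference numbering through a protein
alignment containing a designated reference row. Where the reference has a
gap in the relevant column, the position has no exact reference
coordinate; the package reports the nearest preceding reference residue
and flags the label unmappable rather than guessing. The reference row
must already be the mature protein; signal-peptide trimming is the user's
responsibility, because numbering by a precursor would silently shift
every label.

Two labels are treated as the same intron only when codon number and phase
letter agree exactly. Labels one codon apart with equal phase are reported
as distinct with a proximity warning: positions are exact markers, and
merging near-misses would manufacture false homology. Published size
tables in gene families occasionally disagree with their own flanking
labels modulo 3; the consistency check in `exon_length_between()` is there
to surface such conflicts instead of propagating them.

## Event inference

**Dollo parsimony.** Intron gains are modelled as unique events: one gain,
any number of losses. The gain is placed on the branch above the MRCA of
all presence-scored leaves; losses are the maximal branches whose subtrees
contain at least one absent leaf and no present leaf. Leaves scored
unknown — partial gene models, where an undetected intron is more likely a
sequencing artefact than a loss — never force a loss. This is why
`compare_architectures()` refuses to call losses on partial genes and
emits `U` instead.

**Duplications.** On a gene tree whose tips carry species tags, an
internal node is a duplication when its child subtrees share at least one
species. The pipeline estimates the gene tree by neighbor-joining on
p-distances and roots it at the branch minimizing the implied duplication
count (the usual species-overlap practice); on stochastic sequence data
this estimate can over-resolve nearly simultaneous duplications, so exact
truth-log comparisons in the test-suite are made on the reconciled true
gene tree that the simulator can emit directly.

**Dating.** On an ultrametric tree with node ages in MY, an event on a
branch is bracketed by the ages of the branch's ends. The bundled 11-taxon
fixture tree places the actinopterygian stem at 416–360 MY and the
euteleost stem at 231–190 MY, so a duplication on the former and an intron
gain on the latter date exactly to those printed windows. Node ages are
consumed, never estimated: molecular-clock calibration is out of scope.

**Neighbor-joining.** The implementation is the standard Saitou–Nei
agglomeration with two deterministic policies: Q-criterion ties are broken
by the lexicographically smallest pair of cluster representatives, and
negative branch lengths (possible on non-additive input) are clamped to
zero with a warning. On additive matrices the algorithm provably recovers
the generating topology and branch lengths; the suite verifies this on
hundreds of random trees and cross-checks the topology against an
independent NJ implementation.

## Synteny scores and thresholds

Loci are compared as ordered symbol arrangements within a window of `k`
genes per side (default 7, the largest flank size commonly tabulated).
The Jaccard index measures marker sharing; the adjacency score is the
fraction of A's ordered adjacent pairs (including the two pairs touching
the focal gene) recurring in B, so it is 1 exactly when A's window is an
ordered sub-arrangement of B's. Markers present on opposite sides of the
focal gene are classed shuffled, not lost. Orientation is recorded but
ignored by the scores, because gene order, not strand, is the conserved
signal at this scale.

"Conserved with some variations" has no standard quantification, so the
paralog-set signature rule is an explicit package decision: a symbol
belongs to a set's signature when present in at least half of the set's
loci, ordered by median rank; a locus that retains at least half of the
signature while lacking the focal gene is reported as a focal-gene loss.
Both thresholds are visible, documented arguments.

## Sequence features

Per-column conservation is the modal residue frequency with gaps counted
in the denominator but never as the mode (the shading convention of
classic alignment viewers), binned on integer-rounded percentages into
90–100, 70–89, 50–69 and <50. The canonical-residue checklist scores
conserved (≥50% of sequences), partial (>0 and <50%) and missing (0).
RCL sites P17–P1′ are anchored on the reference row; the hinge call uses
the standard serpin criterion that at least 75% of P15–P9 residues are
small (G/A/S/T/V) — collagen-chaperone serpins fail it, which is the
expected non-inhibitory result. Percent identity excludes every column
with a gap in either row and is reported to the integer. All cutoffs are
arguments, not constants.

## The simulator: what it emulates and what it does not

`simulate_gene_family()` evolves a single-copy focal gene down a species
tree under the simplest exchangeable substitution model: per-site Poisson
events at a configured rate (substitutions/site/MY), each replacing the
residue uniformly among the 19 alternatives. This gives the closed-form
identity curve `1/20 + (19/20) exp(-(20/19) * rate * 2 * depth)`
(`calibrate_identity()`), which is how default rates were chosen: at the
default 5.25e-4 subs/site/MY, two lineages separated at the 416 MY root
depth sit in the low-to-mid 60s percent identity, matching the conserved
ortholog range for this family (60–77%). The default history is the study
scenario: introns at coding offsets 574/673/900 (labels 192a/225a/300c for
a reference-collinear gene), two duplications on the actinopterygian stem
producing three paralog sets, and gains at offsets 107 and 305 (36b/102b)
on the euteleost stem of the first copy only. Scripted events are spaced
evenly along their branch so consecutive duplications are separated in
time. Intron lengths are drawn log-uniformly from 78–2096 nt, the span of
intron sizes observed across vertebrate members of this family. The
C-terminal tetrapeptide is held invariant, emulating purifying selection
on the ER-retention signal; this biases realized identities upward by
under half a percentage point at the default protein length (4 invariant
sites in 402) and is neglected by the calibration check's ±3-point
tolerance.

Deliberate non-realism: no rate heterogeneity among sites or lineages, no
codon model, no selection elsewhere, and sequence evolution is indel-free
by default so that reference projection is exact (codon-indel events are
available and the emitted alignment is the true homology, fractional site
bookkeeping included). Passing tests therefore demonstrate the
correctness of the mapping and inference logic under known homology, not
robustness to alignment error on real data — aligner-induced errors are an
input problem this package intentionally leaves upstream.

Coordinate conventions: internally all models are 0-based half-open and
normalized to transcription order at parse time, so downstream logic never
branches on strand; GFF3 I/O converts to and from the standard 1-based
inclusive form. When a gene carries several transcripts, the longest
complete CDS is kept, with lexicographic transcript-ID tie-break. The stop
codon is counted in CDS and terminal-exon lengths (a terminal exon of 303
bp encodes 100 residues plus stop), matching how exon sizes are
conventionally printed. 5' UTR extents may be recorded on a model but are
not part of the coding architecture.

## Problem sizes and determinism

The shipped validation suite runs entirely on constructed and simulated
data: exhaustive phase-arithmetic checks to offset 300, NJ recovery on 200
random 5–8-taxon additive matrices, Dollo-oracle equivalence on random
trees up to 12 leaves, 20 scripted simulator histories of 6–12 species
with up to 2 duplications and 3 gains, 50-replicate identity calibration,
and the full 160,000-case ER-motif enumeration. Every stochastic step
flows from explicit seeds; the same seed reproduces fixtures byte for
byte, and pipeline reruns on identical inputs write identical stage
outputs (verified by manifest content hashes).

## Known limitations

- Loss inference is conservative by construction: absence in a partial
  gene is unknowable, and unknown-only subtrees never contribute losses,
  so loss counts are lower bounds under heavy missingness.
- The species-overlap duplication rule cannot distinguish a duplication
  from incomplete lineage sorting or gene-tree estimation error; on
  estimated trees it should be read as an upper bound.
- Conservation binning on alignments dominated by gap columns depends on
  the gaps-in-denominator decision; alternative conventions can shift
  columns across bin boundaries.
- Reference-gap positions are deliberately unmappable rather than
  interpolated; gappy references yield fewer comparable labels.
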