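---
title: "Structure-based Helitron annotation and comparative polymorphism typing"
author: "heliscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structure-based Helitron annotation and comparative polymorphism typing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heliscan)
```

## The biological problem

Helitrons are Class II transposons that are hard to annotate because they
lack the terminal inverted repeats most DNA transposons carry. What they do
share is a small structural signature: the dinucleotide `TC` at the 5'
terminus, a `CTRR` motif at the 3' terminus, a GC-rich stem-loop (hairpin) of
roughly 15–20 bp a short distance upstream of the 3' end, and a strong
preference to insert between an `A` and a `T` (occasionally between two Ts)
without creating a target site duplication. Non-autonomous family members
carry no coding sequence at all and can only be recognized by this signature
plus homology to a family consensus.

heliscan packages the complete desk-scale workflow around these rules: scoring
structural evidence at candidate intervals, k-mer seeded homology search with
the classic length/identity filters, paired-termini scanning for putative
mother elements, tandem-repeat bloc segmentation, consensus building, family
classification by terminal identity, and — the analytical endpoint —
presence/absence polymorphism typing between two genomes with an activity
extrapolation. A seeded synthetic-genome generator with a planted truth table
makes every stage testable without any external download.

The synthetic defaults emulate a high-copy non-autonomous rice family: a
~2 kb element (default 1993 bp) with a low-GC tandem Bloc A (six ~137 bp
units, GC 0.20, starting near position 80), a moderately GC-rich Bloc B (six
~152 bp units, GC 0.40, starting near position 950), a 16 bp hairpin ending
13 bp upstream of the 3' terminus, and `TC`/`CTAG` termini.

## Structural evidence

`call_candidate()` evaluates four independent criteria on the strand of the
query interval and returns all flags plus their count (0–4); filtering on the
score is deliberately left to the caller, so weak candidates remain visible.

The hairpin detector enumerates every stem/loop placement (default stems
5–9 bp, loops 3–8 bp, total length restricted to 15–20 bp) whose last base
falls 4–35 bp upstream of the 3' terminus. Stems pair by Watson–Crick rules
only (no G:U), with at most one mismatch; the stem must be at least 60 % G/C.
The published window for the hairpin position is "10–12 bp" generically and
13 bp for the rice family, so the search window is kept generous and the
offset is *reported*, not filtered — hard-coding a fragile constant would
make the detector family-specific.

Ranking among passing placements is deterministic: most stem G:C pairs,
fewest stem mismatches, largest total length, smallest 3' offset, then the
longer stem of an equivalent decomposition. The mismatch criterion sits
second on purpose: without it, any perfect stem can be "beaten" by the same
stem extended one base into a mismatch (equal G:C pairs, greater length), so
a perfect planted hairpin would never be reported with its own geometry. The
final stem-length criterion only resolves stem/loop splits of the exact same
window (a 17 bp window can parse as stem 7 + loop 3 or stem 6 + loop 5).

`offset_3p` counts the bases after the hairpin's last base up to and
including the terminal base: an element ending `...hairpin + 9 spacer bp +
CTAG` has `offset_3p = 13`, i.e. "13 bp upstream of the 3' end".

Ambiguity policy: `N` fails every motif position, never pairs in a stem, and
never matches in a seed or alignment identity — ambiguous sequence can only
lower, never raise, the evidence for a candidate.

## Homology search

`seeded_local_hits()` finds exact shared 12-mers, clusters them by diagonal
(single linkage, band ±16, at least 2 seeds), and realigns the query against
each clustered subject window by optimal local alignment (match +1, mismatch
−1, gap −2). After the best alignment in a window, the flanking sub-windows
are searched recursively, so several homologous segments in one region (for
example a consensus split apart by extra repeat units) are all reported. Hits
must reach 80 bp aligned length and 80 % identity (matches over alignment
columns) — the classic annotation filters — and both strands are searched.
This is a seed-and-extend design in the BLAST family, but the extension step
is an optimal windowed alignment rather than an x-drop heuristic: at the
window sizes involved the exact computation is affordable and it makes the
oracle equivalence in the test suite (full Smith–Waterman on small
instances) meaningful rather than approximate.

`merge_hits()` collapses hits whose subject intervals lie within 200 bp of
each other (per strand, transitive closure) — the fragment-merging rule used
when annotating high-copy families. `paired_termini_scan()` reproduces the
mother-element search: the first 50 bp and last 80 bp of the consensus serve
as probes (hit thresholds relaxed to 80 % of probe length), and 5'/3' hit
pairs on the same strand, in the correct order, within 25 kb are paired
greedily nearest-first so each hit is used once. Nested or overlapping
candidates are emitted only when their hits are disjoint.

`terminal_identity()` aligns terminal windows globally and divides matches by
the window length, so two 30 bp termini differing at two positions give
28/30 = 93.3 %. Family membership requires 80 % identity over both 30 bp
termini; sub-family membership additionally requires 80 % over both 100 bp
termini. The sub-family threshold is an interpretation — the criterion in the
literature is asserted from identities of that magnitude without an explicit
cut-off — and both thresholds are arguments.

## Tandem blocs and fingerprints

`self_matches()` computes all maximal exact self-match runs (default k = 10)
per lag — the text form of a self dot-plot, exportable as TSV.
`detect_tandem_blocs()` groups matches by lag: matches at one lag that tile a
region define a candidate bloc with unit length equal to the lag. Candidates
are weighted by *matched* base pairs (not by the footprint span between the
two copies, which would systematically favor harmonics at 2× or 3× the true
unit); overlapping candidates are resolved by largest coverage, preferring
the smallest lag that reaches 80 % of the best coverage. This collapses
harmonics onto the fundamental period and reports a dinucleotide
microsatellite at lag 2 (labeled `microsatellite` when the refined unit is
below the 20 bp minimum). Unit counts are real-valued (partial terminal units
are normal in slippage products) and compared with a 0.5-unit tolerance.
Period estimation by modal lag was chosen over autocorrelation or suffix
structures because it is the simplest method with an exactly checkable
brute-force oracle.

`fingerprint()` reduces an element to its bloc architecture — ordered
(label, unit length, unit count, orientation) — using a label library built
from the first element fingerprinted in a run. Because tandem phase differs
between copies, a bloc's representative unit is matched against the *doubled*
library unit by local alignment (rotation-tolerant) on both strands;
60 % identity reuses a label. The fingerprint records both order and
orientation, so either reading of "reversed bloc order" (reordered or
reverse-complemented) is representable.

## Consensus building

`cluster_copies()` is greedy center-based clustering (threshold 80 %
global identity to the center) with a fixed processing order — longest copy
first, ties by id — which makes the partition deterministic.
`build_consensus()` uses a center-star multiple alignment: every member is
aligned to the representative, gaps are projected ("once a gap, always a
gap"), and each column takes its majority symbol. Columns where the gap is
the strict majority are dropped — consensus length depends on this rule, so
it is stated; base ties break toward the center's symbol, then
alphabetically. Center-star is adequate at the ≥80 % identities where
clustering places members, needs no external aligner, and its failure modes
(misplaced indels near gaps) are washed out by the majority vote, as the
seeded recovery test demonstrates (a 600 bp seed sequence is recovered
exactly from twenty copies mutated at 2 %).

Where a family consensus is needed from sub-type consensi, both routes —
pooling all copies or aligning the per-cluster consensi — are possible with
these functions; the pooled route is the default in `consensus_by_cluster()`
because it weights columns by copy support rather than by sub-type.

## Polymorphism typing between two genomes

`classify_locus()` types an orthologous locus pair against the family
consensus:

1. **Element in both loci.** Repeat fingerprints are compared with a shared
   label library: identical architecture within 0.5 units is `shared`,
   anything else `repeat_variation` — the dominant class in comparative
   surveys, produced by replication slippage and unequal crossing-over
   rather than transposition.
2. **Element in exactly one locus** (homology covering ≥50 % of the
   consensus; the other side below that). The carrier's flanks are anchored
   in the empty locus by local alignment. Missing junction-side anchor
   sequence of ≥5 bp is an `excision_flank_deletion`. Otherwise the bases
   between the anchors are inspected: ≤3 bp (alignment end-trimming jitter)
   is a clean junction, called `insertion` when the junction reads A^T or
   T^T and no 4–10 bp target site duplication flanks the element; a
   consensus-homologous fragment of ≥30 bp at ≥80 % identity is
   `excision_incomplete`; a non-homologous insert of up to 500 bp is
   `excision_filler` (filler DNA).
3. **Element in neither locus**: `empty_shared` when the loci align at
   ≥90 % identity.
4. Anything failing the flank checks folds into `unresolved` rather than
   forcing a class.

Polarity — insertion into A versus excision from B — is inferred from site
morphology alone: a clean A^T junction is read as an insertion, a repair
footprint as an excision. Without an outgroup genome this is a heuristic,
not a strict inference, and it is reported as such (the carrier genome is a
field of the call). The residual/flank/filler thresholds are package
defaults exposed in `polymorphism_params()`; the qualitative patterns they
operationalize are the classic double-strand-break repair footprints.

`estimate_activity()` is the closing arithmetic: of `inspected` manually
typed sites, `true_polymorphic` are genuine presence/absence events; the
fraction (to one decimal, half away from zero) extrapolated over
`total_sites` gives the mobilized-copy estimate. `estimate_activity(856,
148, 8)` prints 5.4 % and 46.

## The synthetic-data generator

The generator is first-class, tested code, not a fixture. `make_element()`
renders the canonical structure with the bloc unit consensus carrying its
target GC *exactly* (shuffled fixed composition), each unit copy diverged at
the bloc's rate (0.02 for Bloc A, 0.05 for the "less conserved" Bloc B). The
hairpin stem is all-G/C with non-pairing `A` guards on both sides, and the
rendered element is verified to make the planted hairpin the detector's
unique optimum (re-drawn otherwise). The default hairpin is stem 6 + loop 4
= 16 bp — the published total length with a geometry consistent with
`total = 2·stem + loop`.

`plant_elements()` places copies in i.i.d. background sequence (default GC
0.43, grass-genome scale) at A^T dinucleotides with ≥1 kb spacing.
`diverge_pair()` realizes a divergence specification: genome A receives new
insertions, genome B realizes excisions with uniform footprint geometry
(residual 30–300 bp, flank deletion 5–50 bp, filler 5–200 bp), repeat
variants change one bloc by ±1–3 units, and both genomes receive independent
point mutations. The default rate, 0.01 per bp, is the order of neutral
divergence between rice species that split a few hundred thousand years ago.
The default class counts (4 insertions, 4 excisions split 2 incomplete /
1 flank deletion / 1 filler, 120 repeat variants, 20 intact shared copies —
148 loci) mirror a comparative survey in which most candidate polymorphisms
turn out to be repeat-number variation.

What the generator does *not* emulate: isochore/GC structure, indel
mutations outside the modeled footprints, segregating variation within a
species, nested insertions, and the empirical size distribution of real
sub-types (1.2–2.7 kb, driven by bloc counts; `element_size_variant()`
covers size variation but with a random interior). Passing tests therefore
demonstrate correctness of the *method* under controlled conditions, not
performance on real genomes.

## Numerical choices and reproducibility

* Alignments use `Biostrings::pairwiseAlignment` throughout, with a gap of
  length L costing `open + ext·L`. Schemes: hits and terminal windows
  +1/−1/−2 linear; clustering/consensus +1/−1 with gaps 3+L; locus
  alignment +1/−2 with affine 6+0.5L, tuned so a whole missing element is
  one indel block. The affine convention is pinned by a Gotoh oracle in the
  tests.
* Identity denominators differ by design: terminal identity divides by the
  window length (28/30 = 93.3 %); hit and pairwise identities divide by
  alignment columns.
* Percentages are reported to one decimal, extrapolations to the nearest
  integer, both rounded half away from zero (matching printed survey
  numbers; base `round()` would round half to even).
* Every stochastic entry point takes a `seed`; the RNG state is restored
  afterwards, and identical seeds give byte-identical genomes, truth tables
  and output files (FASTA wrapped at 60 columns).
* Degenerate inputs: empty sequences reverse-complement to themselves; a
  window larger than the sequence yields an empty GC profile with a
  warning; elements at a sequence edge fail the insertion-site rule with a
  warning; classification failures fold into `unresolved`, never errors.

## Problem sizes in the test suite

The suite validates the heuristics against brute-force oracles at sizes
where the oracles are exact and fast: Smith–Waterman comparisons on 1.5–3 kb
subjects, all-pairs self-match enumeration on ~200 bp structured sequences,
hairpin enumeration on 60 bp windows (200 random draws), consensus recovery
from 20 × 600 bp copies over 20 trials, and classification truth-recovery on
simulated pairs of 8–17 loci (clean: exact; 1 % noise: ≥90 %). These sizes
are the package's own choices for a suite that a developer runs on every
change; the operations themselves scale to the full default simulation
(148 loci, ~0.5 Mb genomes), as in the `simulate`/`compare` CLI example.

## Known limitations

* The seeded search needs two exact 12-mers on a diagonal band; homology
  below ~75 % identity or shorter than ~40 bp can escape seeding even though
  the final filters would admit it at 80 bp/80 %.
* The windowed local alignment reports at most one alignment per recursion
  branch; heavily interleaved repeats can shadow minor homologies inside an
  already-aligned region.
* Insertion/excision polarity is a site-morphology heuristic (see above);
  with an outgroup genome it could be made identifiable, which is out of
  scope here.
* `cluster_copies()` is greedy; near-threshold copies join the first
  qualifying center rather than a globally optimal partition.
* The classifier assumes pre-extracted orthologous loci; whole-genome
  alignment is out of scope.
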