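# heliscan

Structure-based annotation and comparative analysis of Helitron transposons
in R.

Helitrons are Class II (DNA) transposons that lack terminal inverted repeats
and are recognized instead by a small structural signature: a 5' `TC`
dinucleotide, a 3' `CTRR` motif, a GC-rich stem-loop (hairpin) of 15–20 bp
just upstream of the 3' terminus, and insertion between an `A` and a `T`
(or two Ts) with no target site duplication. Non-autonomous family members
carry no coding sequence, so this signature — plus homology to a family
consensus — is all there is to find them, and comparing their occupancy
between two related genomes is how their recent activity is measured.

heliscan is for sequence analysts studying plant (or other) Helitron
families at desk scale. It provides:

* **Structural evidence** — `call_candidate()` scores an interval for the
  four hallmarks; `find_hairpin()` enumerates stem/loop placements (stems
  5–9 bp, loops 3–8 bp, total 15–20 bp, Watson–Crick pairs only, ≤1
  mismatch, stem GC ≥ 0.6) and reports the best by a deterministic
  parsimony-first ranking; `validate_insertion_site()` checks the A^T rule.
* **Homology search** — `seeded_local_hits()` (exact 12-mer seeds on
  diagonal bands, optimal local realignment per window, hits filtered at
  80 bp / 80 % identity), `merge_hits()` (200 bp fragment merging),
  `paired_termini_scan()` (50 bp/80 bp terminal probes paired on one strand
  within 25 kb — the mother-element search), `terminal_identity()` and
  `classify_family()` (80 % over the terminal 30 bp for a family, 80 % over
  100 bp for a sub-family).
* **Repeat structure** — `self_matches()` (dot-plot as data),
  `detect_tandem_blocs()` (period from the modal self-match lag, per-bloc
  GC, harmonic-safe), `fingerprint()` (bloc architecture used to separate
  repeat-number variation from true polymorphism).
* **Consensus building** — `cluster_copies()` (greedy center-based, 80 %)
  and `build_consensus()` (center-star MSA, majority rule, gap-majority
  columns dropped).
* **Comparative polymorphism** — `classify_locus()` types an orthologous
  locus pair as `shared`, `repeat_variation`, `insertion` (clean A^T
  junction, no TSD), one of three excision footprints
  (`excision_incomplete`, `excision_flank_deletion`, `excision_filler`),
  `empty_shared`, or `unresolved`; `estimate_activity()` extrapolates
  family-wide activity from a manually typed subset.
* **Synthetic data** — `make_element()`, `plant_elements()`,
  `diverge_pair()` / `simulate_pair()`: a fully seeded generator of
  Helitron-like elements (default: 1993 bp, low-GC tandem Bloc A of six
  137 bp units at GC 0.20, Bloc B of six 152 bp units at GC 0.40, a 16 bp
  hairpin ending 13 bp upstream of the 3' end, `TC`/`CTAG` termini) and of
  diverged genome pairs with a planted truth table.

## Worked example

Generate a default synthetic element and inspect its structure:

```r
library(heliscan)

elem <- make_element(seed = 42)
nchar(elem)
#> [1] 1993

find_hairpin(as.character(elem), nchar(elem))
#> hairpin: 16 bp (stem 6 + loop 4), 6 G:C pairs, 0 mismatch(es),
#>   stem GC 1.00, ends 13 bp upstream of the 3' terminus [1965-1980]

detect_tandem_blocs(as.character(elem))
#>   start  end unit_length unit_count   mean_gc covered  label
#> 1    80  895         137       5.96 0.2058824     746 tandem
#> 2   962 1847         152       5.83 0.4051919     714 tandem
```

The element is 1993 bp, carries the canonical 16 bp hairpin 13 bp upstream
of its 3' terminus, and its two tandem blocs are recovered with the planted
unit lengths (137/152 bp), unit counts (≈6) and GC contents (≈0.20/0.40).

Simulate a diverged genome pair with planted truth and type every
orthologous locus:

```r
pair <- simulate_pair(divergence_spec(n_insertions = 2, n_excisions = 4,
                                      n_repeat_variants = 3, n_shared = 3),
                      seed = 7)
loci  <- orthologous_loci(pair)
calls <- classify_loci(loci, pair$consensus)
table(truth = loci$class, called = calls$klass)
#> every off-diagonal count is zero: 2 insertions, 2 incomplete excisions,
#> 1 flank-deletion, 1 filler, 3 repeat variations, 3 shared — all recovered

estimate_activity(856, 148, 8)
#> 8 of 148 inspected sites are true polymorphisms (5.4%)
#> extrapolated over 856 candidate sites: ~46 mobilized copies
```

The last call is the activity arithmetic for a survey in which 148 of 856
candidate polymorphic sites were manually typed and 8 proved to be genuine
presence/absence events: 5.4 % of sites, or about 46 mobilized copies
family-wide.

The same stages are scriptable from a shell via the bundled CLI
(`inst/cli/heliscan.R`), with subcommands `simulate`, `scan`, `annotate`,
`consensus`, `compare`, and `estimate`; every run echoes its effective
configuration to `heliscan.log` in the output directory.

```sh
Rscript inst/cli/heliscan.R simulate --seed 7 --out-dir sim/
Rscript inst/cli/heliscan.R compare --genome-a sim/genome_a.fasta \
    --genome-b sim/genome_b.fasta --loci sim/truth.tsv \
    --consensus sim/consensus.fasta --out-dir sim/
Rscript inst/cli/heliscan.R estimate --total 856 --inspected 148 --polymorphic 8
```

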