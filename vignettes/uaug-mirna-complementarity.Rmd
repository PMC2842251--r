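---
title: "Scanning upstream AUG motifs for microRNA complementarity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scanning upstream AUG motifs for microRNA complementarity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uaugscan)
```

## The question

Upstream AUG triplets (uAUGs) in 5'-UTRs repress translation of the
downstream open reading frame, and that repression is often cell-type
specific even though the mRNA is present everywhere.  MicroRNAs repress
translation too, and their expression *is* cell-type specific.  `uaugscan`
implements a sequence-level test of the hypothesis that connects the two:
that uAUG-centered motifs act as binding sites for the 5' or 3' halves of
mature miRNAs, so that the repressive activity of a uAUG in a given cell
line tracks the presence of a complementary miRNA.  The package takes
pairwise human/mouse 5'-UTR alignments and a mature miRNA catalog, finds
uAUG-centered motifs, screens every motif x miRNA-half combination with a
two-step complementarity filter, and asks — against a composition-preserving
shuffle null — whether motifs pair with miRNA halves more often than chance,
stratified by miRNA end, miRNA conservation and motif conservation.

## Motif extraction

Every AUG in the gap-stripped human 5'-UTR counts as a uAUG (the curated
alignment inputs are leader sequences only, so no Kozak-context filtering
is applied, and overlapping AUGs each yield a motif).  The motif window
runs from 4 nt upstream of the A through 4 nt downstream of the G — an
11-mer with the AUG at offset 4 — clipped at the sequence bounds; clipping
may remove flank positions but never the AUG, and windows shorter than
7 nt are discarded.  A motif is *conserved* when the mouse row of the
alignment is 100% identical over the motif's columns: any substitution,
any mouse gap under a motif base, or any mouse insertion inside the span
breaks the call.  This is the strictest reading of cross-species identity;
it is judged on the alignment columns as given, never by re-aligning.
Coordinates are 0-based half-open internally and 1-based only in written
reports, which keeps the window arithmetic free of off-by-one cases.

## The miRNA catalog

A focal-species miRNA is *conserved* when a miRNA with the same base name
(the name after the species prefix, compared exactly and
case-insensitively, arm suffixes included) exists in another species —
nucleotide identity is irrelevant to this call.  Mature sequences are
split into a 5' half and a 3' half; for odd lengths the extra nucleotide
goes to the 5' half, which keeps the canonical seed (positions 2-7) inside
the 5' half for every mature length from 16 nt up.  The opposite
convention (extra nucleotide to the 3' half) is defensible — some published
3'-half match motifs are one nucleotide longer than a floor-half allows —
and can be obtained by splitting upstream of `catalog_halves()`; the
package fixes one rule so results are reproducible.

## The two-step screen

For each motif x half pair (motif 5'→3' against the half antiparallel),
`longest_complementary_stretch()` finds the maximum run of consecutive
paired positions where every pair is Watson-Crick or G:U, with at most
`max_gu` wobbles inside the run.  Ties are broken by fewer wobbles, then
smaller motif start, then smaller half start, so output is deterministic.
A candidate passes when the stretch reaches `min_stretch` (default 7 nt)
*and* the stretch's hybridization free energy at 37 °C passes `dg_cutoff`
(default −14 kcal/mol).  Genome-wide runs use the same wobble allowance at
both ends (0 or 1); gene-level reports allow one wobble at the 3' end and
none at the 5' end.

The energy model scores the fully paired stretch with Turner 2004
nearest-neighbor stacking terms plus a +0.5 kcal/mol penalty for each
helix end closed by A:U or G:U; the parameter file is versioned and
shipped as plain TSV (`inst/extdata/energy_turner2004.tsv`).  Two
deliberate choices need stating:

* **No bimolecular initiation term by default.**  Reported energies are on
  the scale customary for duplex-screening tools, which omit the ~+4.1
  kcal/mol initiation constant; the −14 default cutoff is calibrated to
  that scale.  Setting `duplex_init = 4.1` reproduces the full Turner
  scale exactly — the test suite verifies agreement with `RNAduplex` to
  the printed digit on G/C-closed duplexes.
* **No bulges or internal loops.**  Because the decision-relevant quantity
  downstream is the consecutive stretch, the energy is computed on that
  ungapped stretch only.  This is the largest simplification in the
  package relative to a full hybridization search: a short perfect match
  embedded in a longer, bulged duplex scores worse here than a loop-aware
  tool would score the whole duplex.  Consequently AU-rich 7-mers cannot
  reach −14 kcal/mol under any physically sane stack table (six AU-type
  stacks sum to roughly −6 to −10), and published 7-mer interactions whose
  energies were evidently computed over larger duplexes will not pass this
  screen.  The worked example below shows both outcomes.

```{r let7d}
half3 <- split_halves("AGAGGUAGUAGGUUGCAUAGUU")$three_p  # let-7d 3' half
for (m in c("AACUAUG", "ACUAUGCAA", "CUAUGCAAC")) {
  s <- longest_complementary_stretch(m, half3, 0)
  dg <- duplex_free_energy(substr(m, s$motif_span[1] + 1, s$motif_span[2]),
                           substr(half3, s$half_span[1] + 1, s$half_span[2]))
  cat(sprintf("%-10s stretch %d  dG37 %6.2f kcal/mol  pass: %s\n",
              m, s$stretch_len, dg, dg <= -14))
}
```

The two 9-mers pass; the 7-mer pairs perfectly over its full length but
stays well above the cutoff.

## Shuffle null and Z-test

Each shuffle iteration permutes every focal miRNA's full mature sequence
(a mononucleotide, composition-preserving shuffle), re-derives the halves
from the shuffled sequence, re-runs the scan, and records interaction
counts per stratum.  The shuffle-then-split order matters and is pinned by
a regression test: shuffling halves separately preserves per-half
composition, shuffling the full sequence does not, and the two nulls are
not interchangeable.  Iteration *i* draws from a stream seeded with
`seed + i`, so the null is reproducible and independent of execution
order.  Significance is a one-sided upper-tail Z-test of the observed
count against the null mean and sample SD (n−1); a degenerate null
(SD = 0) yields p = 0, 0.5 or 1 by the sign of the difference and is
flagged.  No multiple-testing correction is applied across the strata by
default, matching the original design; `bonferroni = TRUE` adds an
adjusted column.

Two caveats on the normal assumption.  Stratum counts are small,
right-skewed and clustered (one GC-rich half can hit many motifs), so the
Z-test can run anti-conservative when the null mean is well below ~1-2
counts; and the full-sequence shuffle slightly under-disperses half
composition relative to observed halves.  The package's calibration check
(200 unplanted synthetic datasets, null stratum mean ~1-2) keeps the
empirical false-positive rate inside the binomial 99% band around 0.05,
but for sparser designs the empirical-quantile p-value over the recorded
null counts (`null_model$counts`) is the safer diagnostic.

## Gene-level reports

Gene analyses start from explicit 7-11 nt uAUG windows (published tables
print the windows, not the full UTRs) plus optional mutated windows.
Mutants need not contain an AUG and run through exactly the same search
path — the mutant flag exists only for reporting, so a mutation changes
results only through complementarity.  Hits are restricted to conserved
miRNAs, annotated with repression folds (1x-6x, transcribed from the
cited reporter experiments — these are data, never computed) and with
cell-line expression evidence (expressed / not expressed / unknown when no
record exists).  Windows with no predicted miRNA appear as explicit "None"
rows.  The bundled miRNA file for the worked KLF9 example
(`mirna_snapshot_synthetic.fa`) is a synthetic stand-in, not a miRBase
release: the let-7d entry is the well-known mature sequence, and the other
entries are constructed to satisfy the published motif-complementarity
constraints, with flanks invented.  Conclusions drawn from it validate the
pipeline's behavior, not the historical catalog.

## The synthetic-data generator

`simulate_dataset()` generates the statistical structure the analysis
assumes, with known ground truth:

* UTR pairs: uniform-composition human sequences (GC fraction
  configurable), background AUGs scrubbed, a Poisson(`uaug_rate`) number
  of AUGs injected at spaced positions; the mouse row is a per-column copy
  with substitution rate 1 − `column_conservation_rate`, and no indels, so
  generated alignments are gap-free (gap handling is exercised by
  hand-built fixtures instead).
* miRNAs: random sequences, 20-22 nt; each is duplicated under a second
  species prefix with ~10% divergence with probability
  `conserved_mirna_fraction` (a Bernoulli draw per miRNA).
* Planted sites: for each full-window uAUG, with probability `plant_rate`
  the surrounding sequence is overwritten with the exact reverse
  complement of an eligible conserved 3' half, placed so that one of the
  site's AUG triplets lands on the uAUG.  A half is eligible at an offset
  when the overlap with the motif window reaches the stretch minimum and
  the overlap duplex passes the energy screen — so every planted triple is
  recoverable by construction, and the sensitivity-1.0 check tests the
  scanner rather than the energy model.  The mouse row is synchronized
  over the affected span, keeping planted motifs conserved.  Ineligible
  halves are skipped and counted.  Importantly, unplanted catalogs carry
  no imposed structure at all: an earlier design that seeded AUG-complementary
  triplets into every generated half made even unplanted data
  systematically enriched against its own shuffle null, and was discarded
  for exactly that reason.

Default generator values are the package's reference study conditions:
200 UTRs of 50-300 nt, 2.05 expected uAUGs per UTR (the motifs-per-UTR
mean of the curated human/mouse alignment census), per-column conservation
0.97 (an 11-mer survives intact with probability 0.97^11 ≈ 0.72, matching
the reported ~70-75% conserved 11-mers), 70 focal miRNAs with expected
conserved fraction 5/7, plant rate 0.2.  What passing tests on these data
do *not* show: real 5'-UTRs have composition biases, indel-containing
alignments and paralogy structure that the generator deliberately omits,
so recovery and calibration results here bound implementation correctness,
not biological performance.

## Validation problem sizes

The test suite validates the stretch finder against an
exhaustive-enumeration oracle on 10,000 random pairs (lengths ≤ 12, all
wobble allowances 0-2), the energy engine against `RNAduplex`, planted
recovery and stratum significance on the 200-UTR reference study with 100
shuffle iterations, and null calibration on 200 unplanted datasets of 150
UTRs x 50 miRNAs with 50 iterations each — sizes chosen so the null
stratum mean sits at ~1-2 counts, where the normal approximation the
method assumes is at its weakest defensible point, while a full run stays
a desk-scale computation.

## Known limitations

* Stretch-only energies (no loop-aware rescue of short matches), discussed
  above; the `dg_cutoff` is only meaningful on the bundled
  initiation-free scale.
* Conservation calls are only as good as the input alignments; there is no
  re-alignment and no treatment of alignment uncertainty.
* Name-based miRNA conservation inherits naming-convention quirks across
  species catalogs (arm suffixes are matched literally).
* Expression evidence is consumed as transcribed presence/absence calls;
  the package makes no attempt to re-derive them from primary data, and
  repression folds are annotations, not measurements made here.
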