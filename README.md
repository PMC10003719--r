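# flipmir

Flipons are DNA elements that switch between B-DNA and alternative
conformations under physiological stress: left-handed Z-DNA at alternating
pyrimidine/purine repeats d(YR)n, G-quadruplexes (G4) at d(G3-5X1-7)4,
triplex/H-DNA at purine runs d(R)n, and stress-induced duplex
destabilization (SIDD) at AT-rich d(ATX)n repeats. Conserved microRNA
families carry a 7-nt seed (mature positions 2–8) whose perfect DNA match
(mRS) can occur inside a flipon or at its junction with B-DNA — and,
depending on which strand is bound, promote or suppress the conformational
flip. `flipmir` implements the full analysis of this interaction for
genomicists working with experimentally mapped non-B DNA intervals:

- **Seed matching** — scan genomic regions for perfect 7-mer seed matches
  on both strands (`scan_mrs_matches()`), with either the seed-identity or
  seed-complement orientation convention.
- **Site taxonomy** — classify each match against a flipon by overlap
  length *k*: *k* = 7 is a motif site (M), 2 ≤ *k* ≤ 6 a motif–junction
  site (MJ), *k* = 1 a junction site (J) (`classify_site()`).
- **Feature and regulatory context** — promoter bands (≤1 kb, 1–2 kb,
  2–3 kb), UTR/exon/intron/downstream/distal assignment, and the eight-way
  cCRE / CTCF / LINE-LTR (TRE) category after a ±200 bp extension.
- **Promoter profiling** — flipon and match density in 100 bp windows
  around the TSS (multi-window flipons counted in every window touched),
  coding vs non-coding promoter fractions, and a promoter heptamer census
  distinguishing sliding-window occurrences from distinct flipons.
- **Conformation calls** — G4 is promoted when the G-rich strand and the
  match share a strand ("+,+" or "−,−") and suppressed otherwise; Z-DNA is
  suppressed by a match on either strand; wobble d(G:T) hairpin search
  (`fold_hairpin()`) and Z-quadruplex candidates (GT repeats > 11 bases).
- **Statistics** — Monte-Carlo interval-overlap significance with a
  length-preserving within-chromosome uniform null and pseudocount
  empirical p `(1 + #{null ≥ obs})/(n + 1)`; TSS distance profiles with a
  centered rolling mean; hypergeometric set enrichment with
  Benjamini–Hochberg adjustment.
- **Synthetic data** — `build_synthetic_dataset()` generates a
  two-chromosome genome with planted flipon consensus motifs, gene models,
  regulatory tracks, miR families and seed-match sites at controlled
  M/MJ/J offsets, together with a machine-readable truth manifest, so the
  whole pipeline is testable end to end at zero tolerance.

All coordinates are 0-based half-open (BED convention); GTF input is
converted at the I/O boundary.

## Worked example

The `analysis/` scripts run the whole study on the synthetic dataset:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_match_classify.R
```

which prints

```
wrote dataset to results/synthetic
  flipons: 200 (G 50, H 40, S 60, Z 50)
  planted mRS sites: 82
  SIDD mean length: 169.8 bp
  miR families: 20 (16 conserved)
82 flipon-associated seed matches (44 M, 26 MJ, 12 J)
flipons with at least one conserved-family match: 72 of 200
strand balance at promoter sites: coding 14, template 17 (no strong preference expected)
```

Every planted site is recovered with its intended class: M sites sit fully
inside a flipon, MJ sites span an end with 2–6 shared bases, and J sites
touch exactly one base at the 5′-end −6 bp or 3′-end +6 bp placement. The
remaining stages annotate features and regulatory context
(`03_annotate_features.R`), profile promoters — coding promoters hold
24.5% of all flipons versus 8.5% for non-coding ones, while gene bodies
reverse the order (16.0% vs 23.0%) — and take the heptamer census
(`04_promoter_profiles.R`), test AGO-peak/promoter overlap — 50 of 80
AGO-like peaks overlap proximal promoters, Monte-Carlo p ≈ 0.001 at
n = 1000 (`05_overlap_stats.R`) — and call conformation effects: all 26 Z
calls suppress, the 21 G4 calls split 8 promoting / 13 suppressing by
strand, 12 Z flipons fold into hairpins only when G:T wobble pairs are
allowed, and 11 carry GT runs long enough to be Z-quadruplex candidates
(`06_conformation_reports.R`, which also writes per-gene promoter reports
with sequence alignments).

In code, the core loop is:

```r
library(flipmir)
ds <- build_synthetic_dataset(default_synthetic_config(seed = 101))
matches <- scan_mrs_matches(ds$genome, ds$flipons, ds$mirs)
matches <- classify_matches(matches, ds$flipons)
table(matches$site_class[matches$site_class != "none"])
#>  J  M MJ
#> 12 44 26
```

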