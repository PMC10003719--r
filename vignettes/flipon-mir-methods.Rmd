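---
title: "Methods: microRNA seed targeting of non-B DNA flipons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: microRNA seed targeting of non-B DNA flipons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flipmir)
```

## The model

Flipons are genomic elements that exchange B-DNA for an alternative
conformation when the local topology supplies the energy: alternating
pyrimidine/purine repeats d(YR)n flip to left-handed Z-DNA, four G-runs
d(G3-5X1-7)4 fold one strand into a G-quadruplex (G4), purine runs d(R)n
form triplex/H-DNA, and AT-rich d(ATX)n repeats undergo stress-induced
duplex destabilization (SIDD, the S class). A microRNA's seed — mature
positions 2–8, a 7-mer — can match one DNA strand of such an element
perfectly. The analysis this package implements asks where those matches
fall (inside the motif, at its junction with B-DNA, or both), on which
strand relative to transcription, in what genomic and regulatory context,
and what each interaction implies for the conformational flip.

Three conventions anchor everything:

* **Coordinates** are uniformly 0-based half-open. BED input is native;
  GTF is converted on parsing. Two intervals overlap when they share at
  least one base pair, so half-open adjacency is not overlap. A
  minus-strand gene's TSS is the rightmost base of its span — the standard
  convention, stated here because annotation formats leave it implicit.
* **Seed orientation.** A matching strand can be read two ways: the strand
  whose sequence *is* the seed (identity convention) or the strand the miR
  would *base-pair with* (complement convention). Both 7-mers are carried
  for every family (`mrs_identity`, `mrs_target = revcomp(mrs_identity)`)
  and the scanner takes a `mode` argument; the default is `identity`,
  matching the strand-labelling used when figures describe a strand
  "matching the seed sequence". Because the scanner always searches both
  genomic strands, the two modes yield the same set of sites with strand
  labels swapped — the choice matters only for how strand preference is
  reported.
* **Site classes.** With `k` the number of bases a 7-mer shares with a
  flipon interval: `k = 7` → M (motif), `2 ≤ k ≤ 6` → MJ (motif–junction),
  `k = 1` → J (junction), `k = 0` → none. For a flipon of length ≥ 7 the
  only J placements are the 5′-end −6 bp and 3′-end +6 bp. A flipon
  shorter than 7 bp cannot host an M site; the same `k` rule still
  applies, an edge case the source material never addresses and which we
  resolve by keeping the classification a pure function of `k`.

## Parameters that matter

| parameter | default | unit | role |
|---|---|---|---|
| promoter extent (`up`, `down`) | 1000, 1000 | bp | proximal promoter = TSS ± 1 kb, strand-aware |
| window width | 100 | bp | TSS profile resolution; flipons touching two windows count in both |
| regulatory extension (`ext`) | 200 | bp | flipons extended each side before cCRE/CTCF/TRE overlap |
| downstream window | 3000 | bp | "Downstream" feature label past the gene 3′ end |
| Monte-Carlo iterations (`n_iter`) | 1000 | — | null shuffles for overlap significance |
| rolling-mean window | 8 | elements | smoothing of TSS distance profiles |
| `min_stem`, `min_loop` | 4, 3 | nt | hairpin feasibility minima, conventional values |

Feature assignment anchors each interval at its midpoint — deterministic
even for long SIDDs — and resolves competing labels by the priority
promoter bands > 5′UTR > 3′UTR > exon > intron > downstream > distal
intergenic, the precedence conventional peak annotators use. Both the
anchor and the priority vector are arguments.

## Conformation logic

For a G flipon the G-rich strand is the structure-forming strand. When a
seed match lies on that same strand ("+,+" or "−,−") the miR engages the
complementary C-rich strand's partner and the quadruplex is free to form:
the call is *promotes*, with the structure on the G-rich strand. Opposite
strands give *suppresses*. The rule is invariant under simultaneous
inversion of both strands and independent of transcription direction. For
Z flipons any match suppresses the flip, on either strand; junction-class
sites act by blocking the B–Z junction, whose flanking sequence is more
variable than the repeat itself, so the site class is carried in the call.
S and H flipons receive no call — no strand rule is defined for them.
Where the source figure legend additionally maps promoted G4 onto
coding/template strand colour codes, the legend's colour rule conflicts
with its own definition of the transcription arrow; rather than guess, the
package reports the genomic `structure_strand` alongside the gene's strand
and leaves the coding/template readout to the caller.

The wobble-hairpin search (`fold_hairpin()`) enumerates every loop
placement and extends a contiguous stem while pairs are Watson–Crick
(A:T, G:C) or, when allowed, the non-canonical G:T wobble that is fully
compatible with Z-DNA. Stems are contiguous — no bulges — because the
folds under study are short, ungapped repeat arms; ties prefer the
shorter loop, then the leftmost fold. `z_compatible` requires both arms to
alternate purine/pyrimidine. A strand containing an uninterrupted
alternating-GT run longer than 11 bases is flagged as a Z-quadruplex
candidate instead (`zq_candidate()`), after the left-handed quadruplex
described for long r(GT)n repeats.

## Statistics

The Monte-Carlo overlap test counts how many intervals of set B touch set
A, then re-places each B interval uniformly on its own chromosome (length
preserved, placements independent) `n_iter` times. This within-chromosome
uniform null is the simplest defensible one; it is deliberately pluggable,
and it ignores GC and annotation structure — a GAT-style matched null is
out of scope. The empirical p uses the pseudocount estimator
`(1 + #{null ≥ obs})/(n_iter + 1)`, which can never return 0. Under a true
null the p-values are approximately uniform; the test suite checks this
with a Kolmogorov–Smirnov test over 200 replicates, using a B set large
enough (500 intervals) that the integer-valued overlap count takes many
distinct values — with few intervals the discreteness of the statistic,
not any flaw in the estimator, makes the p-value distribution visibly
lumpy.

Distances to the nearest peak measure to the nearest *contained* base of a
half-open interval (`end − 1`), never the exclusive end coordinate. The
rolling mean is centered; at the series edges windows truncate rather than
pad, so the output keeps the input length. With the default even width of
8 a perfectly symmetric full window does not exist; the implementation
uses the `zoo` convention (offsets −3…+4).

Gene-set enrichment is an upper-tail hypergeometric test with
Benjamini–Hochberg adjustment across terms. It stands in for web-service
annotation tooling whose knowledgebase and modified-Fisher score are not
reproducible offline; published FDR values from that service are therefore
not comparison targets.

## The synthetic generator

`build_synthetic_dataset()` emulates the study's inputs at desk scale: two
1 Mb chromosomes of i.i.d. uniform ACGT background, 60 genes (40 coding,
20 noncoding) in the first ~70% of each chromosome with ≥ 2.2 kb between
neighbouring genes so promoters never collide, and ~200 flipons written
over the background from per-class consensus templates (Z: one d(YR)
dinucleotide repeated, 12–40 bp; G: four G-runs of 3–5 with 1–7 bp non-G
spacers, on a random strand; H: purine runs of 20–50; S: d(ATX)n with
length drawn around a 170 bp mean, the empirical mean size of mapped
SIDDs). Placement fractions are the study conditions: ~24.5% of flipons in
coding proximal promoters versus 8.5% in noncoding ones, 16% versus 23%
over gene bodies, with the repeat-element SIDDs inside LINE/LTR-labelled
TREs flanked by AT-run target-site-duplication-like sequence. AGO-like
peaks are placed with a 60% promoter bias so the overlap test has known
signal.

Planted seed-match sites must be the *only* occurrences of their 7-mers:
exact-count recovery tests demand zero background hits. No 7-mer is
spontaneously unique in 4 Mb of uniform sequence (each expects ~240
occurrences), so the generator rescans the genome for every family 7-mer
in both orientations and resamples one base of each stray occurrence,
iterating until clean. Mutable bases are chosen outside planted site
windows — sites keep a ≥ 2 base gap, so a stray window always has one —
and outside flipon motifs when possible; a flipon whose interior had to be
edited, or that hosts a planted site, loses its `pristine` flag, and the
consensus-regex property test runs only on pristine flipons. Palindromic
seeds and cross-family identity/complement collisions are redrawn so every
hit identifies one family and one strand unambiguously.

The truth manifest records every planted element plus expected summary
tables computed from the planted coordinates by direct brute-force
arithmetic, separate from the pipeline's vectorised code paths. The
end-to-end test writes the dataset to files, runs the full pipeline on
those files, and requires exact equality — same seed, zero tolerance.

What passing these tests shows is internal consistency at genome-scale
mechanics: format round-trips, both-strand scanning, overlap taxonomy,
strand bookkeeping and window arithmetic. What it does not show is
robustness to real-data messiness — non-uniform base composition, nested
and overlapping repeats, ragged experimental interval boundaries, assembly
gaps — none of which the generator simulates.

## Numerical and scale choices

The default problem size (2 × 1 Mb, 200 flipons, 82 planted sites, 20
families) generates in under ten seconds and runs the full pipeline in
about as long, which keeps the complete test suite and the acceptance
script comfortably reproducible on a laptop; all sizes are config fields.
Monte-Carlo calibration in the tests uses 200 replicates at
`n_iter = 200`; the headline overlap test uses the conventional
`n_iter = 1000`. Heptamer counting reads the transcription-oriented strand
of each promoter (single strand), merging overlapping same-strand
promoters first so shared sequence is counted once; both decisions are
flags (`both_strands`, `merge`) because the conventions behind published
promoter heptamer totals are not stated, and flipon heptamer content is
read from the plus strand. 7-mers containing N are skipped everywhere, and
N never matches in a scan.

## Known limitations

* One label per flipon in feature assignment; an element spanning a
  promoter and an exon reports only the higher-priority label.
* The cCRE track is not subtyped (no PLS/pELS/dELS), and CTCF is whatever
  BED the caller supplies — cCRE-derived flag or independent ChIP track.
* No mismatch or wobble tolerance in seed matching (perfect 7-mers only),
  no 6-/8-mer site types, no thermodynamics.
* The hairpin search reports a single best fold; suboptimal folds and
  bulged stems are out of scope.
* Assembly liftover is out of scope; all inputs must share one assembly.
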