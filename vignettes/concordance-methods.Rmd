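---
title: "Methods: Sov-based concordance of ERV annotations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Sov-based concordance of ERV annotations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ervconcord)
```

This vignette documents the model behind `ervconcord`, the choices made
where the design was genuinely open, and what the synthetic-data tests do
and do not demonstrate about real annotation data.

## The problem and the coordinate model

Locus-resolved repeat annotations of the same genome disagree for two
qualitatively different reasons: genuine disagreement about whether a
locus exists, and representational disagreement about how one locus is
stored. The dominant representational effect for LTR retroelements is
defragmentation: a curated source may store one record per biological
element, spanning all of its collinear fragments *including* the gaps
between them, while RepeatMasker-derived sources store one record per
fragment. Any criterion that demands near-total mutual overlap will
therefore misread representational differences as biological ones.

All records are held in a single internal convention: 0-based, half-open
intervals, so that `length = end − start` and two intervals that merely
touch do not overlap. Input dialects are converted on read (1-based
inclusive input: `start − 1`; RepeatMasker `.out`: `begin − 1`, strand
`C` → `−`). The convention was fixed by requiring that coordinates
printed in genome-browser style (`chr1:48 138 333–48 140 169`) reproduce
their printed lengths exactly as `end − start`, with no ±1 adjustment;
`parse_locus_string()` enforces this identity. Chromosome names are
matched exactly after trimming — no `chr`-prefix repair — because a
silent naming fix would corrupt concordance counts; mismatches surface
as zero overlaps, which is auditable.

Strand and family identity are deliberately ignored by the matcher:
matching is purely coordinate-based, and cross-superfamily coordinate
matches are reported as a diagnostic column (`cross_superfamily`)
rather than being excluded.

## The matching criterion

For an overlapping pair s₁, s₂:

$$Sov = \frac{minov + \delta}{maxov},\qquad
\delta = \min\{\,maxov - minov,\; minov,\; \mathrm{cap}(s_1),\; \mathrm{cap}(s_2)\,\}$$

with `minov` the intersection length and `maxov` the union span. Two
variants of the per-segment cap are implemented:

* **`as_printed`** — `cap(s) = len(s)`. In this form `Sov = 1` exactly
  when the overlap reaches half the longer segment's length (for
  a ⊆ b: `Sov = 1 ⇔ len(a) ≥ len(b)/2`, an identity the test suite
  verifies exhaustively).
* **`half_capped`** (default) — `cap(s) = len(s)/2`, the cap used in the
  original segment-overlap literature for protein secondary structure.
  For a ⊆ b this gives `Sov = 1 ⇔ len(a) ≥ (2/3)·len(b)`.

The two variants genuinely differ, and descriptions of the statistic in
circulation are not always internally consistent between the formula
written down and the worked values reported alongside it. We default to
`half_capped`, the cap defined in the statistic's original literature:
on the package's reference example, the `LOR1-int` pair, it yields
Sov = 2407/2931 ≈ 0.82, whereas the uncapped form saturates at exactly
1.0 for the same pair and so cannot distinguish this kind of shifted
overlap. Both variants are exposed, every report records which one was
used, and the halves are kept real-valued (no flooring; at the
precision of any reported value this makes no difference).

A pair is **matched** when `Sov ≥ 1`, or — secondary criterion — when
`minov ≥ 0.95 · min(len(s₁), len(s₂))`, i.e. the overlap covers at least
95% of the smaller record (at most a 5% coordinate shift). The
secondary clause exists because a fragment shorter than half of a
merged record can never reach Sov = 1 against it, however perfectly it
is contained. Matching is many-to-many; counting is per record ("has at
least one matched partner"), which makes the pairwise cells of the
report asymmetric by design. Record counts and percentages are reported
with the *counted* source as denominator, to one decimal place.

Per source, the three-way decomposition classifies each record as
shared-in-all (matched in both other sources), matched-in-exactly-one,
or unique (matched in neither); these three classes partition every
source exactly, an invariant the tests enforce.

### Open choices resolved

* **bp totals** are sums of matched-record lengths, not merged genomic
  union — the simpler quantity and consistent with summing per-record
  lengths elsewhere; `total_coverage(mode = "merged_union")` provides
  the alternative for any set.
* **Matching is not restricted to same-superfamily pairs**; the
  coordinate-only definition is retained and cross-superfamily matches
  are merely flagged.
* **Overlap enumeration** is delegated to `GenomicRanges::findOverlaps()`
  (an interval-tree join); the test suite validates it against an
  independent brute-force all-pairs oracle on randomized fixtures, so
  the fast path is never its own referee.

## Classification

Superfamily assignment (ERV1, ERV2, ERV3, Gypsy, Unclassified) is a pure
table lookup: a mapping TSV with columns `family`, `superfamily`,
`group`, `role`, `ignored`. Matching of family names is exact and
case-sensitive after trimming; `-int` suffixes are never auto-stripped,
so LTR and internal names must both be enumerated — fuzzy matching would
trade silent misclassification for convenience. Families absent from the
map, and families flagged `ignored` (orphan internal regions without
LTRs and vice versa), follow `orphan_policy`: labelled `Unclassified`
(default, appropriate for third-party data) or dropped (the preset for
reproducing a curated pipeline that sets orphan types aside). The audit
returned with every classification reconciles exactly:
`n_assigned + n_unmapped + n_ignored_orphans = n_records`. A small
synthetic example map ships as
`inst/extdata/family_map_synthetic.tsv`; it illustrates the layout and
is not a curated resource.

## Descriptive statistics

* Coverage: `sum_lengths` (default) or `merged_union`; the union is
  never larger, with equality iff the set has no internal overlaps.
* Length histograms use uniform half-open 100 bp bins with an overflow
  bucket for records *strictly* longer than 2500 bp — a record of
  exactly 2500 bp stays in the histogram, matching the strict reading
  of "longer than".
* Destruction (the percentage of consensus nucleotides lost; the
  complement of a "completeness" attribute, converted as
  `100 − completeness` with the conversion logged) is summarized only
  over records that carry it, with `n` always reported. Quantiles use
  linear interpolation between order statistics
  (`stats::quantile(type = 7)`); box-plot-style tables per length bin
  come from `destruction_by_length()`, which emits empty bins with
  `n = 0` rather than dropping them.
* Megabase values are bp / 10⁶ rounded to one decimal; destruction
  histograms default to 2-percentage-point bins.

## The synthetic-data generator

`simulate_annotations()` emits one merged-style source (**M**) and two
fragment-style sources (**F1**, **F2**) over a toy genome
(3 chromosomes, 75 Mb), with a complete element→record truth table. It
emulates the statistical structure the analysis depends on:

* **Length mixture** (per element): 20% short degraded fragments
  (uniform 50–250 bp), 60% solo LTRs (equal-weight normal modes at
  250 ± 40 and 450 ± 60 bp), 20% internal/proviral spans (log-normal,
  median 1600 bp, clamped to 0.6–9 kb). This reproduces the
  characteristic bimodal short-length structure (peaks in the 200–300
  and 400–500 bp bins) with a smaller mode near 1600 bp.
* **Fragmentation**: elements spanning ≥ 600 bp fragment with
  probability 0.3 into 2 + Poisson(0.6) parts separated by 30–300 bp
  gaps (gaps capped at half the span). The merged record covers the
  full span including gaps, so it is strictly longer than the sum of
  its fragments whenever there are ≥ 2 of them — the representational
  effect the secondary criterion targets. The 0.3 rate is an
  explicitly arbitrary default: no quantitative fragmentation-rate
  estimate was available to calibrate against.
* **Noise**: per-boundary Gaussian jitter (sd 10 bp), whole-record
  shifts of 300 bp with probability 0.02 (emulating
  detection-algorithm disagreement), 2% per-record dropout, and 5%
  per-source injected unique records placed in reserved genomic slots.
* **Destruction** (source M only, mirroring the one resource that
  carries the attribute): records ≤ 250 bp draw from a high mode
  (100·Beta(8,2), mean ≈ 80%), longer records from a low mode
  (100·Beta(2,8), mean ≈ 20%). Filtering at 250 bp therefore removes
  the second mode — the structure the destruction summaries are
  designed to expose.

Elements never overlap each other (placement reserves disjoint slots),
which keeps truth-based precision well defined; nested and overlapping
repeats, realistic family composition, sequence content and
insertion-age structure are *not* modelled. Passing the simulation
tests therefore demonstrates that the matching machinery behaves as
specified under fragmentation, jitter, shift, dropout and uniques — not
that any particular real database pair will reach a particular
concordance level. All randomness flows from one root seed through
named substreams (placement, fragmentation, jitter, dropout,
destruction, uniques), so identical parameters give byte-identical
output and single stages can be varied while others stay fixed. The
default parameter file ships at
`inst/extdata/sim_params_default.yaml` and is the reference for the
distribution-shape tests.

## Validation against planted truth

`recovery_metrics()` scores a source pair by **sensitivity** (elements
represented in both sources for which at least one record pair matched)
and **precision** (matched pairs linking records of the same element).
Under the default study conditions (10 700 elements): a noiseless run
is recovered perfectly under the combined criterion; Sov-only loses the
fragmented elements; and sensitivity degrades monotonically along shift
grids, and monotonically within a small tolerance along jitter grids —
jitter can occasionally *extend* a record and rescue a borderline pair,
so per-pair monotonicity is not exact.

## Problem sizes and runtime choices

The test suite exercises full-size simulations (10 700 elements,
~36 000 records across the three sources) for the acceptance-style
checks and scaled-down triples (≈ 800–5 350 elements) for
property-style loops; the brute-force overlap oracle runs on 100
random fixtures of up to 500 records per side. These sizes keep the
whole suite under a minute while leaving every assertion at the scale
where the asserted distributional features are stable.

## Known limitations

* The matcher resolves *whether* records correspond, not which source
  is right; no merging or re-defragmentation is attempted.
* Coverage comparisons default to summed record lengths; sources with
  heavy internal overlap should be compared with `merged_union`.
* Whether a "completeness" attribute is exactly `100 − destruction` is
  source-dependent; the converter is a documented, logged default, not
  a claim about any particular database.
* The generator's genome is unrealistically clean (no nesting, uniform
  placement); a nesting-aware generator would be needed to study
  precision under overlapping insertions.
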