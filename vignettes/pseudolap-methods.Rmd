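---
title: "Methods: scoring, classifying and collapsing pseudogene–lncRNA overlaps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring, classifying and collapsing pseudogene–lncRNA overlaps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pseudolap)
library(dplyr)
```

## The problem and the model

Pseudogenes are genomic copies of genes that have lost coding ability —
either intronless retrotransposition products ("processed") or duplicated
gene bodies ("unprocessed"). Because a pseudogene retains high sequence
similarity to its parental gene, any transcription across it, particularly
antisense transcription driven by an overlapping long non-coding RNA, can
feed sequence-specific regulation of the parental gene. `pseudolap` works
entirely at the annotation level: its inputs are gene structures (exon
coordinates and strands), not reads or sequences, and its claim is
positional — *these two annotated transcripts share these exonic bases in
this relative orientation* — never expressional.

Every analysis step is a table transformation. A set of gene models is a
tibble with one row per exon record (`source`, `chrom`, `start`, `end`,
`strand`, `gene_id`, `transcript_id`, `attributes`, `file_order`);
coordinates are 1-based and inclusive at both ends, the GTF convention, and
BED inputs are shifted on read. A gene's *span* runs from its minimum exon
start to its maximum exon end. A gene id whose exons sit on more than one
chromosome or strand is split into per-locus models with suffixed ids,
because a single contiguous span is an assumption of the scoring formulas.

## Overlap scoring

Two scores quantify how well two gene structures coincide, both in $[0,1]$,
both equal to 1 exactly for identical coordinates and 0 for disjoint ones:

* **Span–span**: $SS = P_1 \cdot P_2$, the product of the two reciprocal
  span-coverage fractions. The product (rather than, say, a Jaccard index)
  punishes asymmetric containment: a short RNA buried in a long pseudogene
  scores high on one fraction and low on the other.
* **Exon–exon**: each exon pair sharing at least one base contributes
  $E = e_1 \cdot e_2$ (the two covered fractions of the paired exons), and
  $EE = \sum E / TE$, where $TE$ counts the exons of gene 1 plus the exons
  of gene 2 that overlap *no* exon of gene 1. $EE$ is therefore anchored on
  gene 1; the pipeline always passes the pseudogene first, so all reported
  scores are pseudogene-relative.

Two points in the $TE$ definition were genuinely open and are decided here:

1. "Overlapping no exon of gene 1" is read as *< 1 shared base*, not as
   *not coordinate-identical*. Under the exact-identity reading nearly every
   partner exon would inflate the denominator and two nearly identical genes
   would score far below 1, contradicting the intent that identical
   structures score 1. The strict reading remains available via
   `exon_exon_score(..., te_exclusion = "identical")`.
2. When one exon overlaps several partner exons, every positive-overlap pair
   contributes its own $E$ term; no best-pair assignment is attempted.

Duplicate exon intervals contributed by multiple transcripts of one gene are
collapsed before scoring, so transcript redundancy cannot inflate either
numerator or denominator. Overlap computation itself ignores strand;
orientation (`sense` iff strands equal) is reported alongside, because both
orientations are biologically informative and are tabulated separately.

## The chained intersection pipeline

`intersect_models(focal, partner, mode)` marks every focal gene whose span
shares ≥ 1 bp with a partner span (`span` mode); `exon` mode additionally
requires ≥ 1 overlapping exon pair, and the focal gene then *retains only
its matched exons*. `chain_evidence()` intersects an evidence set (cDNAs,
ESTs) against those retained exons — a deliberate narrowing: evidence must
touch the part of the pseudogene that the lncRNA touches, not merely the
gene body.

3′ ESTs are deposited on the strand opposite their transcript's biological
direction, so `normalize_est_orientation()` flips every record tagged
`read_end "3prime"` before chaining (the tag attribute is configurable; the
operation is an involution and never touches coordinates). Skipping this
step visibly corrupts directionality calls — the fixture generator plants
3′-tagged ESTs on the wrong strand precisely so tests can observe the
repair causally.

Per locus and per evidence tier, the directionality call is
`bidirectional` (≥ 1 sense and ≥ 1 antisense partner), `sense_only` or
`antisense_only`. The combined cDNA-and-EST tier keeps loci present in both
tiers and assigns a call only when the same call holds in both tiers
independently; discordant loci (e.g. sense-only in cDNA but bidirectional
in EST) are kept with call `none`. This concordance rule is what makes the
combined row of the directionality matrix sum to fewer loci than either
single-tier row. The *high-confidence* set is the loci bidirectional in both
tiers — always a subset of the any-evidence set, an invariant the test
suite asserts on every fixture.

In the orientation summary, a locus is a "sense overlap" when all its
partners at that level are sense, "antisense" when all are antisense, and a
"complex locus" when partners occur in both orientations. The three
categories partition the locus count by construction. Cross-tier set
operations key loci by pseudogene gene id; positional collapsing is a
separate, later stage, so id-level and locus-level accounting stay
distinguishable.

## Redundancy elimination and catalog merging

Annotation databases frequently list the same pseudogene locus under several
accessions. `cluster_by_position()` single-linkage-clusters overlapping
spans (transitively chained), and `collapse_loci()` keeps one whole original
record per cluster: the member with the lowest span start, ties broken by
file order and then lexicographic gene id — equivalent, for position-sorted
input, to keeping the first entry of the file, but deterministic and
input-order-invariant in general. No merged super-interval is fabricated;
the representative's own exons and attributes survive.

Clustering is strand-agnostic by default: two databases annotating one locus
on opposite strands still describe one locus, and the goal of the merge is
positional non-redundancy. A `strand_aware = TRUE` switch covers the other
reading. `merge_catalogs()` pools any number of catalogs, collapses, and
reports per-source non-redundant counts plus membership cells (which
combination of sources contributed to each merged cluster), the cells
summing exactly to the merged count.

## Overlays and the enrichment test

piRNA support demands ≥ 1 *exonic* shared base — a piRNA inside an intron
does not count — and the per-locus piRNA tally counts distinct piRNA ids on
the locus's (retained) exons; the aggregate mean is taken over supported
loci only. SNP proximity uses a window (default 10 000 bp) inclusive at both
boundaries: a SNP exactly at `span_end + window` hits, one base further does
not, and `window = 0` degenerates to span containment.

The enrichment comparison between two support proportions uses the pooled
two-proportion z-statistic without continuity correction,
$z = (\hat p_1 - \hat p_2)\big/\sqrt{\hat p(1-\hat p)(1/n_1 + 1/n_2)}$,
with a one-tailed p-value from the standard normal tail in the declared
direction. Two numerical choices worth noting:

* The p-value is computed from the exact $z$ via `pnorm()`. Hand
  calculations that pass through a two-decimal normal table move the third
  decimal of $p$; the package does not emulate that rounding.
* When the pooled proportion is 0 or 1 the variance degenerates; $z$ and
  $p$ are reported as `NA` with a warning rather than as infinities.
* Percentages are reported with half-up rounding to two decimals
  (`proportion_percent()`), matching how such support percentages are
  conventionally printed; R's own `round()` rounds half to even and is
  deliberately not used there.

The test's null calibration is checked by simulation (10 000 null
replicates at group size 400, nominal level 0.05) in the acceptance suite.

## What the fixture generator emulates — and what it does not

`fixture_spec()` / `generate_fixture()` build a complete input ecosystem on
a toy genome (three chromosomes, one 30 kb window per planted locus so
structures cannot interact across loci): a pseudogene catalog, lncRNAs
planted sense/antisense/both/intronic per directive, evidence transcripts
realizing a chosen per-tier directionality, 3′-corrupted ESTs, exonic or
intronic piRNAs, SNPs placed inside the span, exactly at the window edge,
or one base beyond, and two synonym catalogs with jittered coordinates plus
private loci for merge tests. Gene geometry: 1–5 exons of 100–400 bp,
introns of 200–800 bp, so spans stay in the few-kb range typical of
processed pseudogenes. Every expectation in the truth table is computed
arithmetically from the planted geometry at generation time, not by calling
the pipeline, and the same spec and seed reproduce byte-identical files.

What passing these tests shows: the interval arithmetic, scoring formulas,
retention rules, orientation bookkeeping, collapse semantics and overlay
logic are implemented as specified. What it does not show: behavior on
genome-scale inputs with nested and antisense-overlapping annotation
(non-planted cross-talk), EST library artifacts (random-primed or
artificial-promoter libraries), assembly/liftover issues, or annotation
error — real-data phenomena the generator deliberately does not model.
Genome-scale catalog counts can therefore not be reproduced here; the suite
substitutes property-based checks (pipeline-equals-truth across seeds,
brute-force per-base oracles for both scores, non-redundancy and
order-invariance of the merge, subset structure of the high-confidence
set).

## Tunable parameters

| parameter | where | default | meaning |
|---|---|---|---|
| `mode` | `intersect_models()` | — | span-level vs exon-level requirement |
| `te_exclusion` | scoring functions | `"any_overlap"` | reading of the $TE$ exclusion clause |
| `window` | `snp_proximity()` | 10 000 bp | SNP flank, inclusive boundaries |
| `strand_aware` | collapse/merge | `FALSE` | whether opposite-strand overlaps are one locus |
| `attr_key` | `normalize_est_orientation()` | `"read_end"` | GTF attribute naming the EST read end |
| `digits` | `write_annotated_gtf()` | 4 | serialization rounding of SS/EE (computation keeps full precision) |
| `prop_3prime_est` | `fixture_spec()` | 0.5 | fraction of planted ESTs tagged 3′ |

## Problem sizes

The shipped test and acceptance runs use 12-locus fixtures across 20 seeds,
1000 random gene pairs for the scoring oracles, 100 random catalog triples
for the merge properties, and 10 000 null replicates for the z-test
calibration — sizes chosen so the whole suite runs in a few minutes on one
core while every code path and boundary case is exercised.

## Known limitations

* Purely positional: no sequence identity, no parental-gene assignment, no
  expression quantification.
* Evidence tiers treat every cDNA/EST record equally; no library-quality
  weighting.
* The combined-tier concordance rule is one defensible reading of
  "support in both tiers independently"; discordant loci are surfaced with
  call `none` rather than silently dropped, so users can re-aggregate under
  a different rule.
* Orientation classification needs a defined strand on both genes; strand
  `"."` input is rejected at parse time rather than guessed.
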