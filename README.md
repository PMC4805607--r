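# pseudolap

Scored genomic intersection of pseudogenes and long non-coding RNAs.

Pseudogenes — degraded genomic copies of protein-coding genes — are
pervasively transcribed, and lncRNAs overlapping them in sense or antisense
orientation are candidate regulators of both the pseudogene and its parental
gene. `pseudolap` finds and quantifies these overlaps from ordinary GTF
annotation sets, grades each pseudogene locus by the strength and
directionality of its transcription evidence (full-length cDNAs and ESTs),
builds positionally non-redundant pseudogene catalogs from multiple
databases, and overlays piRNA and GWAS-SNP annotations with a
two-proportion enrichment test. It is aimed at regulatory-genomics analysts
working with annotation-level (not read-level) evidence.

Everything is a tibble: gene models are exon-level tables, every step takes a
data frame first and pipes into the next, results come with `tidy()`,
`glance()` and `autoplot()` methods.

## The scores

For two genes with genomic spans *S1*, *S2* (min exon start to max exon end,
1-based inclusive coordinates):

* **Span–span score** `SS = P1 × P2`, where `P1` is the fraction of *S1*
  covered by *S2* and `P2` the converse. `SS = 1` iff the spans are
  identical, `0` iff disjoint.
* **Exon–exon score**: every exon pair with ≥ 1 shared base contributes
  `E = (covered fraction of exon 1) × (covered fraction of exon 2)`;
  `EE = ΣE / TE` with `TE` = (# exons of gene 1) + (# exons of gene 2
  overlapping no exon of gene 1). Identical exon structures give `EE = 1`.
* **Orientation**: `sense` iff the two genes share a strand, reported
  relative to the pseudogene.

The pipeline chains intersections: pseudogenes × lncRNAs (exon mode, keeping
only the matched exons), then cDNAs and ESTs against those retained exons.
A locus is *bidirectional* at a tier when it has both sense and antisense
evidence there; the high-confidence set is bidirectional in **both** the
cDNA and the EST tier. 3′ ESTs are strand-flipped before use
(`normalize_est_orientation()`), since they are conventionally deposited on
the strand opposite the transcript.

## Worked example

Score one pseudogene (exons 1–100 and 201–300, `+`) against an antisense
lncRNA (single exon 51–150, `−`):

```r
library(pseudolap)
pg  <- gene_models(source = "pg",  chrom = "chr1", start = c(1, 201),
                   end = c(100, 300), strand = "+", gene_id = "PSG1")
lnc <- gene_models(source = "lnc", chrom = "chr1", start = 51, end = 150,
                   strand = "-", gene_id = "LNC1")
score_overlap(pg, lnc)
#> # A tibble: 1 × 7
#>      p1    p2    ss    te    ee orientation exon_pairs
#>   <dbl> <dbl> <dbl> <int> <dbl> <chr>       <list>
#> 1 0.333     1 0.333     2 0.125 antisense   <tibble [1 × 3]>
```

The lncRNA span covers a third of the pseudogene span and is itself fully
covered (`SS = 0.333`); its exon half-covers pseudogene exon 1
(`E = 0.5 × 0.5 = 0.25`) and the pseudogene has two exons (`TE = 2`), so
`EE = 0.125`.

A full run on a generated fixture (12 planted loci with known structure):

```r
fx  <- generate_fixture(fixture_spec(), tempfile("demo"), seed = 7)
run <- run_intersections(fx$models$pseudogenes_a, fx$models$lncrnas,
                         cdnas = fx$models$cdnas, ests = fx$models$ests)
intersect_summary(run)
#> # A tibble: 4 × 6
#>   file1  file2 exon_exon_gene_ids sense_overlaps antisense_overlaps complex_loci
#> 1 pgA    lnc                   10              4                  3            3
#> 2 pgA v… cDNA                   8              2                  2            4
#> 3 pgA v… EST                   9              3                  1            5
#> 4 pgA v… cDNA…                 8              1                  1            6
directionality_matrix(run)
#> # A tibble: 3 × 4
#>   support_from bidirectional antisense_only sense_only
#> 1 cDNA                     4              2          2
#> 2 EST                      5              1          2
#> 3 EST and cDNA             3              1          1
```

Ten of the twelve pseudogenes have exon-level lncRNA partners (one planted
locus has only a span-level brush, one none at all); the combined row counts
loci whose call agrees across both evidence tiers.

The enrichment statistic, on the published piRNA-support counts:

```r
two_proportion_ztest(367, 1167, 109, 313, direction = "less")
#> Two-proportion z-test (pooled, one-tailed)
#>   group 1: 367 / 1167 (31.45%)
#>   group 2: 109 / 313 (34.82%)
#>   z = -1.1355, one-tailed p (less) = 0.12808
```

A shell front end wraps the same functions:

```sh
exec/pseudolap intersect --focal pg.gtf --partner lnc.gtf --mode exon --out hits.gtf
exec/pseudolap collapse --out nonredundant.gtf --report venn.tsv a.gtf b.gtf c.gtf
exec/pseudolap ztest --x1 367 --n1 1167 --x2 109 --n2 313 --direction less
```

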