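test_that("span-mode intersect marks any span-sharing pair with full scores", {
  focal <- mk_gene("pg1", c(1, 600), c(400, 1000), strand = "+")
  partner <- mk_gene("lnc1", 500, 1500, strand = "-")
  hits <- intersect_models(focal, partner, mode = "span")
  expect_equal(nrow(hits), 1)
  expect_equal(hits$orientation, "antisense")
  expect_equal(hits$ss, (501 / 1000) * (501 / 1001))
  # focal genes with no partner at all are dropped
  lonely <- dplyr::bind_rows(focal, mk_gene("pg2", c(5000), c(5100))) |>
    dplyr::mutate(file_order = dplyr::row_number())
  hits2 <- intersect_models(validate_gene_models(lonely), partner, mode = "span")
  expect_equal(hits2$focal_gene_id, "pg1")
})

test_that("exon mode requires exon overlap and retains only matched exons", {
  focal <- mk_gene("pg1", c(1, 500, 900), c(100, 600, 1000))
  partner <- mk_gene("lnc1", 550, 700, strand = "-")  # hits exon B only
  hits <- intersect_models(focal, partner, mode = "exon")
  expect_equal(nrow(hits), 1)
  kept <- retained_exons(hits)
  expect_equal(kept$start, 500)
  expect_equal(kept$end, 600)
  # retained models reassemble originals restricted to matched exons
  rm <- retained_models(hits)
  expect_equal(nrow(rm), 1)
  expect_equal(rm$gene_id, "pg1")

  # span overlap without exon overlap: absent from exon mode, present in span
  intronic <- mk_gene("lnc2", 150, 450, strand = "-")
  expect_equal(nrow(intersect_models(focal, intronic, mode = "exon")), 0)
  expect_equal(nrow(intersect_models(focal, intronic, mode = "span")), 1)

  # empty input warns and returns an empty result
  empty <- focal[0, ]
  expect_warning(res <- intersect_models(empty, partner), "empty")
  expect_equal(nrow(res), 0)
})

test_that("intersect pairs agree with GenomicRanges span overlaps", {
  set.seed(77)
  focal <- random_gene_models(30, id_prefix = "F")
  partner <- random_gene_models(30, id_prefix = "P")
  hits <- intersect_models(focal, partner, mode = "span")
  sf <- model_spans(focal)
  sp <- model_spans(partner)
  gr_f <- GenomicRanges::GRanges(sf$chrom, IRanges::IRanges(sf$start, sf$end))
  gr_p <- GenomicRanges::GRanges(sp$chrom, IRanges::IRanges(sp$start, sp$end))
  ov <- GenomicRanges::findOverlaps(gr_f, gr_p, ignore.strand = TRUE)
  want <- sort(paste(sf$gene_id[S4Vectors::queryHits(ov)],
                     sp$gene_id[S4Vectors::subjectHits(ov)]))
  got <- sort(paste(hits$focal_gene_id, hits$partner_gene_id))
  expect_equal(got, want)
})

test_that("evidence chaining anchors on retained exons and classifies direction", {
  # pseudogene with two exons; lncRNA hits exon 2 only
  pg <- mk_gene("pg1", c(1, 500), c(100, 600), strand = "+")
  lnc <- mk_gene("lnc1", 550, 700, strand = "-")
  anchored <- intersect_models(pg, lnc, mode = "exon")

  # cDNA overlapping the unmatched exon 1 does NOT support the locus
  cdna_off <- mk_gene("cd_off", 1, 80, strand = "+", source = "cdna")
  expect_equal(nrow(chain_evidence(anchored, cdna_off, "cDNA")), 0)

  # sense + antisense cDNAs on the retained exon: bidirectional
  cdnas <- validate_gene_models(dplyr::mutate(dplyr::bind_rows(
    mk_gene("cd_s", 520, 580, strand = "+", source = "cdna"),
    mk_gene("cd_a", 530, 590, strand = "-", source = "cdna")
  ), file_order = dplyr::row_number()))
  tier <- chain_evidence(anchored, cdnas, "cDNA")
  calls <- classify_directionality(tier)
  expect_equal(calls$call, "bidirectional")
  expect_equal(calls$tier, "cDNA")

  # sense-only evidence
  sense_tier <- chain_evidence(anchored, cdnas[cdnas$gene_id == "cd_s", ], "cDNA")
  expect_equal(classify_directionality(sense_tier)$call, "sense_only")
  anti_tier <- chain_evidence(anchored, cdnas[cdnas$gene_id == "cd_a", ], "cDNA")
  expect_equal(classify_directionality(anti_tier)$call, "antisense_only")
})

test_that("combined tier needs the same call in both tiers; high confidence is bidirectional in both", {
  cd <- tibble::tibble(locus_id = c("L1", "L2", "L3", "L4"),
                       tier = "cDNA", n_sense = c(1, 2, 0, 1),
                       n_antisense = c(1, 0, 2, 0),
                       call = c("bidirectional", "sense_only",
                                "antisense_only", "sense_only"))
  es <- tibble::tibble(locus_id = c("L1", "L2", "L3", "L5"),
                       tier = "EST", n_sense = c(2, 1, 1, 1),
                       n_antisense = c(1, 0, 1, 1),
                       call = c("bidirectional", "sense_only",
                                "bidirectional", "bidirectional"))
  comb <- combine_tier_calls(cd, es)
  expect_setequal(comb$locus_id, c("L1", "L2", "L3"))  # L4/L5 lack a tier
  expect_equal(comb$call[comb$locus_id == "L1"], "bidirectional")
  expect_equal(comb$call[comb$locus_id == "L2"], "sense_only")
  expect_equal(comb$call[comb$locus_id == "L3"], "none")  # discordant
  expect_equal(comb$locus_id[comb$high_confidence], "L1")
})

test_that("summary rows partition loci by orientation and match planted truth", {
  # planted: 2 sense-only, 1 antisense-only, 1 mixed locus -> row (4, 2, 1, 1)
  directives <- tibble::tibble(
    lnc = c("sense", "sense", "antisense", "both"),
    cdna = "none", est = "none", pirna = "none", snp = "none")
  fx <- generate_fixture(fixture_spec(loci = directives), tempfile("fx"),
                         seed = 11)
  run <- run_intersections(fx$models$pseudogenes_a, fx$models$lncrnas)
  smry <- intersect_summary(run)
  expect_equal(smry$exon_exon_gene_ids, 4)
  expect_equal(smry$sense_overlaps, 2)
  expect_equal(smry$antisense_overlaps, 1)
  expect_equal(smry$complex_loci, 1)
  # partition invariant
  expect_equal(smry$sense_overlaps + smry$antisense_overlaps + smry$complex_loci,
               smry$exon_exon_gene_ids)
})

test_that("summary handles an empty intersection as an all-zero row", {
  pg <- mk_gene("pg1", 1, 100)
  lnc <- mk_gene("lnc1", 5000, 6000)
  run <- suppressWarnings(run_intersections(pg, lnc))
  smry <- intersect_summary(run)
  expect_equal(smry$exon_exon_gene_ids, 0)
  expect_equal(smry$sense_overlaps + smry$antisense_overlaps +
                 smry$complex_loci, 0)
})

test_that("monotone filtering: exon mode <= span mode <= focal set; tiers nest", {
  set.seed(301)
  for (seed in 1:5) {
    fx <- generate_fixture(fixture_spec(), tempfile("mono"), seed = seed)
    pg <- fx$models$pseudogenes_a
    span_hits <- intersect_models(pg, fx$models$lncrnas, mode = "span")
    exon_hits <- intersect_models(pg, fx$models$lncrnas, mode = "exon")
    n_focal <- dplyr::n_distinct(pg$gene_id)
    expect_lte(dplyr::n_distinct(exon_hits$focal_gene_id),
               dplyr::n_distinct(span_hits$focal_gene_id))
    expect_lte(dplyr::n_distinct(span_hits$focal_gene_id), n_focal)
    run <- run_intersections(pg, fx$models$lncrnas,
                             cdnas = fx$models$cdnas, ests = fx$models$ests)
    cb <- run[[1]]
    anchored_ids <- unique(cb$anchored$focal_gene_id)
    for (tier in cb$tiers) {
      expect_true(all(unique(tier$focal_gene_id) %in% anchored_ids))
    }
    both_ids <- cb$combined$locus_id
    expect_setequal(both_ids,
                    intersect(unique(cb$tiers$cDNA$focal_gene_id),
                              unique(cb$tiers$EST$focal_gene_id)))
    # every retained exon is genuinely overlapped by some partner exon
    kept <- retained_exons(cb$anchored)
    lnc_ex <- distinct_exons(fx$models$lncrnas)
    for (r in seq_len(nrow(kept))) {
      ols <- overlap_length(kept[r, c("chrom", "start", "end")], lnc_ex)
      expect_gt(max(ols), 0)
    }
  }
})

test_that("annotated GTF lines carry scored partner groups and re-parse", {
  g1 <- mk_gene("pg1", c(1, 201), c(100, 300), strand = "+")
  g2 <- mk_gene("lnc1", 51, 150, strand = "-", source = "lnc")
  hits <- intersect_models(g1, g2, mode = "exon")
  f <- tempfile(fileext = ".gtf")
  write_annotated_gtf(hits, f)
  line <- readLines(f)
  expect_length(line, 1)
  # SS uses the exon-derived span [1,300]: (100/300) * (100/100) = 1/3
  expect_match(line, sprintf("(lnc1:%.4f:antisense:0.1250)", 1 / 3),
               fixed = TRUE)
  reparsed <- read_gtf(f)
  expect_equal(reparsed$gene_id, "pg1")
  expect_equal(reparsed$start, 1)
  expect_equal(reparsed$end, 300)

  # two partners: two groups in input order on one line
  g3 <- validate_gene_models(dplyr::mutate(dplyr::bind_rows(
    g2, mk_gene("lnc2", 230, 280, strand = "+", source = "lnc")),
    file_order = dplyr::row_number()))
  hits2 <- intersect_models(g1, g3, mode = "exon")
  f2 <- tempfile(fileext = ".gtf")
  write_annotated_gtf(hits2, f2)
  line2 <- readLines(f2)
  expect_length(line2, 1)
  expect_match(line2, "\\(lnc1:.*\\) \\(lnc2:.*\\)")
})
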