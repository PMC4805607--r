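test_that("read_gtf groups exon rows into gene models with derived spans", {
  f <- write_gtf_lines(c(
    gtf_line("chr1", 100, 200, "+", "G1"),
    gtf_line("chr1", 400, 500, "+", "G1"),
    # transcript-typed rows must be ignored, not merged into the span
    paste("chr1", "toy", "transcript", 1, 9999, ".", "+", ".",
          'gene_id "G1"; transcript_id "G1.t1";', sep = "\t")
  ))
  m <- read_gtf(f, "toy")
  expect_equal(nrow(m), 2)
  sp <- model_spans(m)
  expect_equal(sp$start, 100)
  expect_equal(sp$end, 500)
  expect_equal(sp$n_exons, 2)

  # two transcripts of one gene: both exon intervals retained under one model
  f2 <- write_gtf_lines(c(
    gtf_line("chr1", 100, 200, "+", "G", tx = "t1"),
    gtf_line("chr1", 150, 300, "+", "G", tx = "t2")
  ))
  m2 <- read_gtf(f2)
  expect_equal(unique(m2$gene_id), "G")
  expect_equal(nrow(distinct_exons(m2)), 2)
  expect_equal(model_spans(m2)$end, 300)
})

test_that("read_gtf rejects malformed lines with the line number", {
  f <- write_gtf_lines(c(gtf_line("chr1", 100, 200, "+", "G1"),
                         gtf_line("chr1", 500, 400, "+", "G2")))
  expect_error(read_gtf(f), "line 2.*start > end")
  f2 <- write_gtf_lines(gtf_line("chr1", 1, 10, "*", "G1"))
  expect_error(read_gtf(f2), "line 1.*strand")
  f3 <- write_gtf_lines(paste("chr1", "toy", "exon", 1, 10, ".", "+", ".",
                              'transcript_id "t1";', sep = "\t"))
  expect_error(read_gtf(f3), "gene_id")
  f4 <- write_gtf_lines("chr1\texon\t1\t10")
  expect_error(read_gtf(f4), "9 tab-delimited columns")
})

test_that("gene ids spanning several chromosomes or strands are split", {
  f <- write_gtf_lines(c(gtf_line("chr1", 1, 100, "+", "G"),
                         gtf_line("chr2", 1, 100, "+", "G")))
  m <- read_gtf(f)
  expect_setequal(unique(m$gene_id), c("G__chr1+", "G__chr2+"))
  expect_equal(nrow(model_spans(m)), 2)
})

test_that("write_gtf round-trips field-by-field through read_gtf", {
  set.seed(41)
  m <- random_gene_models(15, source_tag = "rt")
  f <- tempfile(fileext = ".gtf")
  write_gtf(m, f)
  m2 <- read_gtf(f, "rt")
  expect_equal(as.data.frame(m2), as.data.frame(m))
})

test_that("read_gtf agrees with an independent GTF parser", {
  set.seed(42)
  m <- random_gene_models(10)
  f <- tempfile(fileext = ".gtf")
  write_gtf(m, f)
  ref <- as.data.frame(rtracklayer::import(f, format = "gtf"))
  got <- dplyr::arrange(m, file_order)
  ref <- ref[order(ref$gene_id, ref$start), ]
  got <- dplyr::arrange(got, gene_id, start)
  expect_equal(nrow(ref), nrow(got))
  expect_equal(ref$start, got$start)
  expect_equal(ref$end, got$end)
  expect_equal(as.character(ref$strand), got$strand)
  expect_equal(ref$gene_id, got$gene_id)
})

test_that("deduplicate_ids keeps the first of identical entries and is idempotent", {
  g <- mk_gene("G1", c(1, 201), c(100, 300))
  dup <- validate_gene_models(
    dplyr::mutate(dplyr::bind_rows(g, g), file_order = dplyr::row_number()))
  expect_message(out <- deduplicate_ids(dup), "removed 2")
  expect_equal(nrow(out), 2)
  expect_equal(out$file_order, 1:2)

  # same gene_id, disjoint transcript sets: both retained
  # (oracle: exhaustive pairwise comparison of (gene_id, transcript) keys)
  two_tx <- gene_models(chrom = "chr1", start = c(1, 1), end = c(50, 50),
                        gene_id = "G", transcript_id = c("t1", "t2"))
  keys <- paste(two_tx$gene_id, two_tx$transcript_id)
  expect_true(all(table(keys) == 1))       # oracle: nothing is a duplicate
  expect_equal(nrow(deduplicate_ids(two_tx)), 2)

  # all-unique input passes through unchanged, and the op is idempotent
  u <- random_gene_models(8)
  expect_equal(deduplicate_ids(u), u)
  once <- suppressMessages(deduplicate_ids(dup))
  expect_equal(suppressMessages(deduplicate_ids(once)), once)
})

test_that("3' EST orientation is reverted, involutively, coordinates untouched", {
  est <- mk_gene("E1", c(10, 100), c(50, 160), strand = "+")
  flipped <- normalize_est_orientation(est, read_end = "3prime")
  expect_equal(unique(flipped$strand), "-")
  expect_equal(flipped$start, est$start)
  expect_equal(flipped$end, est$end)
  # 5' and unknown reads unchanged
  expect_equal(normalize_est_orientation(est, read_end = "5prime"), est)
  expect_equal(normalize_est_orientation(est, read_end = "unknown"), est)
  # involution
  twice <- normalize_est_orientation(flipped, read_end = "3prime")
  expect_equal(twice, est)
  # read_end picked up from the GTF attribute field by default
  f <- write_gtf_lines(c(
    gtf_line("chr1", 1, 99, "+", "E3", extra = ' read_end "3prime";'),
    gtf_line("chr1", 200, 299, "+", "E5", extra = ' read_end "5prime";')
  ))
  m <- normalize_est_orientation(read_gtf(f, "est"))
  expect_equal(m$strand[m$gene_id == "E3"], "-")
  expect_equal(m$strand[m$gene_id == "E5"], "+")
})

test_that("point features convert BED to 1-based and map TSV columns", {
  bed <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t99\t100\tpi1", "chr2\t10\t40\tpi2"), bed)
  feats <- read_point_features(bed, "bed")
  expect_equal(feats$position[1], 100)
  expect_equal(feats$start[1], 100)
  expect_equal(feats$end[1], 100)
  expect_equal(feats$start[2], 11)  # 0-based half-open to 1-based inclusive
  expect_equal(feats$end[2], 40)

  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("rsid\tchrom\tpos\ttrait", "rs1\tchr1\t1234\tasthma"), tsv)
  snps <- read_point_features(tsv, "tsv",
                              columns = list(id = "rsid", chrom = "chrom",
                                             pos = "pos", payload = "trait"))
  expect_equal(snps$id, "rs1")
  expect_equal(snps$position, 1234)
  expect_equal(snps$payload, "asthma")
  expect_error(
    read_point_features(tsv, "tsv", columns = list(id = "nope", chrom = "chrom",
                                                   pos = "pos")),
    "no such column")

  empty <- tempfile()
  writeLines(character(), empty)
  expect_equal(nrow(read_point_features(empty, "bed")), 0)
})
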