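# compact constructors for toy gene models used across the suite

mk_gene <- function(id, starts, ends, strand = "+", chrom = "chr1",
                    source = "toy") {
  gene_models(source = source, chrom = chrom, start = starts, end = ends,
              strand = strand, gene_id = id)
}

write_gtf_lines <- function(lines, path = tempfile(fileext = ".gtf")) {
  writeLines(lines, path)
  path
}

gtf_line <- function(chrom, start, end, strand, gene, tx = paste0(gene, ".t1"),
                     feature = "exon", src = "toy", extra = "") {
  paste(chrom, src, feature, start, end, ".", strand, ".",
        sprintf('gene_id "%s"; transcript_id "%s";%s', gene, tx, extra),
        sep = "\t")
}
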