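#' Gene model tables
#'
#' Throughout pseudolap a set of gene models is a plain tibble with one row
#' per exon record and the columns
#' \describe{
#'   \item{source}{annotation-set tag (e.g. the pseudogene or lncRNA set name)}
#'   \item{chrom}{chromosome name}
#'   \item{start, end}{1-based inclusive exon coordinates, \code{start <= end}}
#'   \item{strand}{\code{"+"} or \code{"-"}}
#'   \item{gene_id, transcript_id}{identifiers from the GTF attribute field}
#'   \item{attributes}{the raw GTF attribute column, carried through to output}
#'   \item{file_order}{original row order, used for deterministic tie-breaks}
#' }
#' A gene's \emph{span} is the interval from its minimum exon start to its
#' maximum exon end; [model_spans()] derives one span row per gene.
#'
#' @param source,chrom,start,end,strand,gene_id,transcript_id,attributes,file_order
#'   column vectors, recycled to a common length.
#' @return A tibble with the columns above.
#' @examples
#' g <- gene_models(chrom = "chr1", start = c(100, 400), end = c(200, 500),
#'                  strand = "+", gene_id = "G1")
#' model_spans(g)
#' @export
gene_models <- function(source = "set", chrom, start, end, strand = "+",
                        gene_id, transcript_id = gene_id,
                        attributes = NA_character_, file_order = NULL) {
  out <- tibble(
    source = as.character(source), chrom = as.character(chrom),
    start = as.integer(start), end = as.integer(end),
    strand = as.character(strand), gene_id = as.character(gene_id),
    transcript_id = as.character(transcript_id),
    attributes = as.character(attributes)
  )
  out$attributes <- if_else(
    is.na(out$attributes),
    sprintf('gene_id "%s"; transcript_id "%s";', out$gene_id, out$transcript_id),
    out$attributes
  )
  out$file_order <- if (is.null(file_order)) seq_len(nrow(out)) else as.integer(file_order)
  validate_gene_models(out)
}

model_columns <- c("source", "chrom", "start", "end", "strand",
                   "gene_id", "transcript_id", "attributes", "file_order")

#' @rdname gene_models
#' @param models a gene-model tibble.
#' @export
validate_gene_models <- function(models) {
  missing_cols <- setdiff(model_columns, names(models))
  if (length(missing_cols) > 0) {
    abort(paste0("gene model table lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (any(models$start > models$end)) {
    bad <- which(models$start > models$end)[1]
    abort(sprintf("exon with start > end (row %d: %d > %d)",
                  bad, models$start[bad], models$end[bad]))
  }
  if (!all(models$strand %in% c("+", "-"))) {
    abort("strand must be '+' or '-' for every exon")
  }
  as_tibble(models)
}

#' Derive one genomic span per gene
#'
#' The span runs from the minimum exon start to the maximum exon end of the
#' gene. Exon counts are counted over distinct exon intervals, so duplicate
#' exons contributed by several transcripts of the same gene count once.
#'
#' @param models a gene-model tibble (see [gene_models()]).
#' @return A tibble with one row per \code{gene_id}: \code{source}, \code{chrom},
#'   \code{strand}, \code{start}, \code{end}, \code{n_exons},
#'   \code{transcript_ids} (comma-joined sorted set), \code{attributes} (first
#'   seen) and \code{file_order} (first seen).
#' @export
model_spans <- function(models) {
  validate_gene_models(models)
  per_gene <- models %>%
    group_by(.data$gene_id) %>%
    summarise(
      source = first(.data$source),
      chrom = first(.data$chrom),
      strand = first(.data$strand),
      n_loci = dplyr::n_distinct(paste(.data$chrom, .data$strand)),
      n_exons = dplyr::n_distinct(paste(.data$chrom, .data$start, .data$end)),
      start = min(.data$start),
      end = max(.data$end),
      transcript_ids = paste(sort(unique(.data$transcript_id)), collapse = ","),
      attributes = first(.data$attributes),
      file_order = min(.data$file_order),
      .groups = "drop"
    )
  if (any(per_gene$n_loci > 1)) {
    offenders <- per_gene$gene_id[per_gene$n_loci > 1]
    abort(paste0("gene id(s) span several chromosomes/strands (run ",
                 "split_multi_locus() first): ",
                 paste(head(offenders, 3), collapse = ", ")))
  }
  per_gene %>%
    select(-"n_loci") %>%
    arrange(.data$chrom, .data$start, .data$gene_id) %>%
    relocate("source", "chrom", "start", "end", "strand", "gene_id")
}

#' Split gene ids that map to several chromosomes or strands
#'
#' The overlap-scoring formulas presume one contiguous span per gene, so a
#' gene_id whose exons sit on more than one (chromosome, strand) combination
#' is split into one model per combination, with the id suffixed as
#' \code{<gene_id>__<chrom><strand>}.
#'
#' @param models a gene-model tibble.
#' @return The tibble with suffixed gene ids where splitting was needed.
#' @export
split_multi_locus <- function(models) {
  validate_gene_models(models)
  models %>%
    group_by(.data$gene_id) %>%
    mutate(.n_loci = dplyr::n_distinct(paste(.data$chrom, .data$strand))) %>%
    ungroup() %>%
    mutate(gene_id = if_else(
      .data$.n_loci > 1,
      sprintf("%s__%s%s", .data$gene_id, .data$chrom, .data$strand),
      .data$gene_id
    )) %>%
    select(-".n_loci")
}

#' Distinct exon intervals per gene
#'
#' @param models a gene-model tibble.
#' @return One row per distinct (gene_id, chrom, start, end) exon interval,
#'   sorted by position within gene, with an \code{exon_idx} index.
#' @export
distinct_exons <- function(models) {
  validate_gene_models(models)
  models %>%
    distinct(.data$gene_id, .data$chrom, .data$start, .data$end, .data$strand) %>%
    arrange(.data$gene_id, .data$start, .data$end) %>%
    group_by(.data$gene_id) %>%
    mutate(exon_idx = row_number()) %>%
    ungroup()
}

interval_length <- function(start, end) end - start + 1L
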