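#' Cluster gene models by positional overlap
#'
#' Single-linkage clustering of overlapping genomic spans: two genes belong
#' to the same cluster when their spans share at least one base, directly or
#' through a chain of intermediates. Clustering is strand-agnostic by default,
#' since one pseudogene locus annotated on opposite strands by two databases
#' is still one locus; set \code{strand_aware = TRUE} to cluster within
#' strands. Deterministic for a given input.
#'
#' @param models a gene-model tibble (id-deduplicated).
#' @param strand_aware cluster separately per strand (default FALSE).
#' @return A tibble with one row per gene: span columns plus \code{cluster_id}
#'   (dense integer, ordered by chromosome then cluster start) and
#'   \code{is_representative} (TRUE for the member with the lowest span start;
#'   ties broken by file order, then lexicographic gene id).
#' @examples
#' m <- gene_models(chrom = "chr1", start = c(1, 50, 140), end = c(100, 150, 200),
#'                  gene_id = c("a", "b", "c"))
#' cluster_by_position(m)  # one cluster of 3 by transitive chaining
#' @export
cluster_by_position <- function(models, strand_aware = FALSE) {
  spans <- model_spans(models)
  if (nrow(spans) == 0) {
    return(spans %>% mutate(cluster_id = integer(), is_representative = logical()))
  }
  grp_key <- if (strand_aware) paste(spans$chrom, spans$strand) else spans$chrom
  spans <- spans %>%
    mutate(.grp = grp_key) %>%
    arrange(.data$.grp, .data$start, .data$end, .data$file_order) %>%
    group_by(.data$.grp) %>%
    # a new cluster starts where a span begins beyond every previous end
    mutate(.new = .data$start > dplyr::lag(cummax(as.numeric(.data$end)),
                                           default = -Inf),
           .local = cumsum(.data$.new)) %>%
    ungroup() %>%
    mutate(cluster_id = dplyr::dense_rank(paste0(.data$.grp, "#",
                                                 sprintf("%09d", .data$.local)))) %>%
    group_by(.data$cluster_id) %>%
    arrange(.data$start, .data$file_order, .data$gene_id, .by_group = TRUE) %>%
    mutate(is_representative = row_number() == 1) %>%
    ungroup() %>%
    arrange(.data$chrom, .data$start, .data$gene_id) %>%
    select(-".grp", -".new", -".local")
  spans
}

#' Collapse clusters to one representative locus each
#'
#' Keeps, per cluster, the whole original record of the member with the
#' lowest span start (ties by file order then gene id) — the first entry of a
#' position-sorted GTF. The output is positionally non-redundant: no two
#' output spans overlap. Idempotent.
#'
#' @inheritParams cluster_by_position
#' @return A gene-model tibble restricted to the representative genes.
#' @export
collapse_loci <- function(models, strand_aware = FALSE) {
  clusters <- cluster_by_position(models, strand_aware = strand_aware)
  reps <- clusters %>% filter(.data$is_representative)
  models %>%
    semi_join(reps, by = "gene_id") %>%
    arrange(.data$chrom, .data$start, .data$gene_id)
}

#' Merge pseudogene catalogs into a non-redundant superset
#'
#' Concatenates two or more catalogs, clusters all spans positionally and
#' keeps one representative per cluster, yielding a single positionally
#' non-redundant catalog. The report records, per source, the count after
#' collapsing that catalog alone, the merged non-redundant count, and the
#' membership ("Venn") cells: each merged cluster is assigned to the
#' combination of sources that contributed members to it.
#'
#' @param catalogs a named list of gene-model tibbles (>= 2), one per source
#'   database. Names override the tables' \code{source} tags.
#' @param strand_aware see [cluster_by_position()].
#' @return A list with \code{models} (the merged non-redundant gene-model
#'   tibble) and \code{report}, a \code{catalog_report} tibble with columns
#'   \code{cell} (source combination, \code{"+"}-joined), \code{n_loci}, and
#'   attributes \code{per_source} (tibble of per-source non-redundant counts)
#'   and \code{merged_count}.
#' @export
merge_catalogs <- function(catalogs, strand_aware = FALSE) {
  if (!is.list(catalogs) || is.data.frame(catalogs) || length(catalogs) < 2) {
    abort("merge_catalogs needs a list of at least two catalogs")
  }
  if (is.null(names(catalogs)) || any(names(catalogs) == "")) {
    names(catalogs) <- paste0("catalog", seq_along(catalogs))
  }
  tagged <- purrr::imap(catalogs, function(m, nm) {
    validate_gene_models(m) %>% mutate(source = nm)
  })
  per_source <- purrr::imap(tagged, function(m, nm) {
    tibble(source = nm,
           n_loci = dplyr::n_distinct(collapse_loci(m, strand_aware)$gene_id))
  }) %>% bind_rows() %>% arrange(.data$source)
  # re-number file order so concatenation order only breaks exact ties
  offset <- 0L
  pooled <- purrr::map(tagged, function(m) {
    m2 <- m %>% mutate(file_order = .data$file_order + offset)
    offset <<- offset + nrow(m) + 1L
    m2
  }) %>% bind_rows()
  # same gene id in two catalogs must stay two entries
  pooled <- pooled %>% mutate(gene_id = paste0(.data$source, "|", .data$gene_id))
  clusters <- cluster_by_position(pooled, strand_aware = strand_aware)
  provenance <- clusters %>%
    group_by(.data$cluster_id) %>%
    summarise(cell = paste(sort(unique(.data$source)), collapse = "+"),
              .groups = "drop")
  cells <- provenance %>% count(.data$cell, name = "n_loci") %>%
    arrange(dplyr::desc(.data$n_loci), .data$cell)
  merged <- collapse_loci(pooled, strand_aware = strand_aware) %>%
    mutate(gene_id = sub("^[^|]*\\|", "", .data$gene_id))
  report <- structure(cells,
                      per_source = per_source,
                      merged_count = sum(cells$n_loci),
                      class = c("catalog_report", class(cells)))
  list(models = merged, report = report)
}

#' @export
print.catalog_report <- function(x, ...) {
  cat("Non-redundant catalog merge\n")
  ps <- attr(x, "per_source")
  for (i in seq_len(nrow(ps))) {
    cat(sprintf("  %s: %d non-redundant loci\n", ps$source[i], ps$n_loci[i]))
  }
  cat(sprintf("  merged: %d non-redundant loci\n", attr(x, "merged_count")))
  NextMethod()
}

#' @method tidy catalog_report
#' @export
tidy.catalog_report <- function(x, ...) {
  as_tibble(x)
}

#' @method glance catalog_report
#' @export
glance.catalog_report <- function(x, ...) {
  ps <- attr(x, "per_source")
  out <- tibble(merged_loci = attr(x, "merged_count"),
                n_sources = nrow(ps), n_cells = nrow(x))
  out
}
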