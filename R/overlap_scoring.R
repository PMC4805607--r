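#' Overlap length between closed genomic intervals
#'
#' Intervals are 1-based and inclusive at both ends, so \code{[1,100]} and
#' \code{[101,200]} abut without sharing a base. Strand is ignored; intervals
#' on different chromosomes overlap by 0. Vectorized with recycling.
#'
#' @param a,b data frames with columns \code{chrom}, \code{start}, \code{end}.
#' @return Integer vector of shared base counts.
#' @examples
#' overlap_length(data.frame(chrom = "chr1", start = 100, end = 200),
#'                data.frame(chrom = "chr1", start = 150, end = 250))  # 51
#' @export
overlap_length <- function(a, b) {
  n <- max(nrow(a), nrow(b))
  idx_a <- rep_len(seq_len(nrow(a)), n)
  idx_b <- rep_len(seq_len(nrow(b)), n)
  ol <- pmin(a$end[idx_a], b$end[idx_b]) - pmax(a$start[idx_a], b$start[idx_b]) + 1L
  as.integer(ifelse(a$chrom[idx_a] == b$chrom[idx_b], pmax(0L, ol), 0L))
}

#' Span-span overlap score
#'
#' Scores how well two genes' genomic spans coincide as the product of the two
#' reciprocal coverage fractions: \code{P1} is the fraction of gene 1's span
#' covered by gene 2's span, \code{P2} the converse, and \code{SS = P1 * P2}.
#' The score is 1 exactly when the spans are identical and 0 when they are
#' disjoint (including different chromosomes).
#'
#' @param g1,g2 gene-model tibbles each holding a single gene.
#' @return A one-row tibble: \code{p1}, \code{p2}, \code{ss}.
#' @examples
#' g1 <- gene_models(chrom = "chr1", start = 1, end = 100, gene_id = "a")
#' g2 <- gene_models(chrom = "chr1", start = 51, end = 150, gene_id = "b")
#' span_span_score(g1, g2)  # P1 = P2 = 0.5, SS = 0.25
#' @export
span_span_score <- function(g1, g2) {
  s1 <- model_spans(g1)
  s2 <- model_spans(g2)
  stopifnot(nrow(s1) == 1, nrow(s2) == 1)
  ol <- overlap_length(s1, s2)
  tibble(p1 = ol / interval_length(s1$start, s1$end),
         p2 = ol / interval_length(s2$start, s2$end),
         ss = .data$p1 * .data$p2)
}

#' Exon-exon overlap score
#'
#' Every exon pair with a positive overlap contributes
#' \code{E = (fraction of the gene-1 exon covered) * (fraction of the gene-2
#' exon covered)}. The total unique exon count \code{TE} is the number of
#' gene-1 exons plus the number of gene-2 exons that overlap no gene-1 exon
#' at all, and \code{EE = sum(E) / TE}. Genes with identical exon structure
#' score 1; genes whose exons never touch score 0. The score is defined
#' relative to gene 1 (the pipeline always passes the pseudogene first).
#'
#' Exon sets are reduced to distinct intervals first, so duplicate exons from
#' multiple transcripts of one gene do not inflate \code{TE}.
#'
#' @param g1,g2 gene-model tibbles each holding a single gene.
#' @param te_exclusion how a gene-2 exon qualifies as "sharing coordinates"
#'   with gene 1 for the \code{TE} exclusion: \code{"any_overlap"} (>= 1 bp,
#'   the default) or \code{"identical"} (exact coordinate identity).
#' @return A one-row tibble: \code{te}, \code{ee} and a list-column
#'   \code{exon_pairs} holding one tibble of per-pair scores
#'   (\code{exon1_idx}, \code{exon2_idx}, \code{e}).
#' @examples
#' g1 <- gene_models(chrom = "chr1", start = c(1, 201), end = c(100, 300),
#'                   gene_id = "a")
#' g2 <- gene_models(chrom = "chr1", start = 51, end = 150, gene_id = "b")
#' exon_exon_score(g1, g2)  # one pair with E = 0.25, TE = 2, EE = 0.125
#' @export
exon_exon_score <- function(g1, g2, te_exclusion = c("any_overlap", "identical")) {
  te_exclusion <- match.arg(te_exclusion)
  e1 <- distinct_exons(g1)
  e2 <- distinct_exons(g2)
  stopifnot(dplyr::n_distinct(e1$gene_id) == 1, dplyr::n_distinct(e2$gene_id) == 1)
  pairs <- tidyr::crossing(i = e1$exon_idx, j = e2$exon_idx) %>%
    mutate(ol = overlap_length(e1[.data$i, ], e2[.data$j, ]))
  pos <- pairs %>% filter(.data$ol > 0) %>%
    mutate(e = (.data$ol / interval_length(e1$start[.data$i], e1$end[.data$i])) *
             (.data$ol / interval_length(e2$start[.data$j], e2$end[.data$j])))
  if (te_exclusion == "any_overlap") {
    matched2 <- unique(pos$j)
  } else {
    matched2 <- e2$exon_idx[paste(e2$chrom, e2$start, e2$end) %in%
                              paste(e1$chrom, e1$start, e1$end)]
  }
  te <- nrow(e1) + (nrow(e2) - length(matched2))
  tibble(
    te = as.integer(te),
    ee = sum(pos$e) / te,
    exon_pairs = list(pos %>% select(exon1_idx = "i", exon2_idx = "j", "e"))
  )
}

#' Relative orientation of two gene models
#'
#' \code{"sense"} when the two genes lie on the same strand, otherwise
#' \code{"antisense"}. Reported relative to the first gene, which in the
#' pipeline is always the pseudogene.
#'
#' @param g1,g2 gene-model tibbles each holding a single gene.
#' @return \code{"sense"} or \code{"antisense"}.
#' @export
relative_orientation <- function(g1, g2) {
  s1 <- unique(g1$strand)
  s2 <- unique(g2$strand)
  stopifnot(length(s1) == 1, length(s2) == 1)
  if (s1 == s2) "sense" else "antisense"
}

#' Full overlap score for one gene pair
#'
#' Convenience wrapper combining [span_span_score()], [exon_exon_score()] and
#' [relative_orientation()].
#'
#' @inheritParams exon_exon_score
#' @return A one-row tibble: \code{p1}, \code{p2}, \code{ss}, \code{te},
#'   \code{ee}, \code{orientation}, \code{exon_pairs}.
#' @export
score_overlap <- function(g1, g2, te_exclusion = "any_overlap") {
  dplyr::bind_cols(
    span_span_score(g1, g2),
    exon_exon_score(g1, g2, te_exclusion = te_exclusion)
  ) %>%
    mutate(orientation = relative_orientation(g1, g2), .before = "exon_pairs")
}
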