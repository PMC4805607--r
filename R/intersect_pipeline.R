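#' Intersect two annotation sets with span and exon scoring
#'
#' Every focal gene whose genomic span shares at least one base with a partner
#' gene's span is marked as intersecting; one annotation row is produced per
#' (focal gene, partner gene) pair, carrying the span-span score, the
#' exon-exon score and the orientation of the partner relative to the focal
#' gene. In \code{"exon"} mode a pair additionally needs at least one exon
#' pair with a positive overlap, and the focal gene retains only the exons
#' that matched a partner exon (retrievable with [retained_models()]). Focal
#' genes with no qualifying partner are absent from the result.
#'
#' @param focal,partner gene-model tibbles (id-deduplicated; see
#'   [deduplicate_ids()]). The pipeline passes the pseudogene set as
#'   \code{focal}, so scores and orientations are pseudogene-anchored.
#' @param mode \code{"span"} or \code{"exon"}.
#' @param te_exclusion passed to the exon-exon score; see [exon_exon_score()].
#' @return A tibble of class \code{pg_hits}, one row per pair, sorted by
#'   (chrom, focal span start, focal gene id): columns \code{focal_gene_id},
#'   \code{partner_gene_id}, \code{chrom}, \code{focal_start},
#'   \code{focal_end}, \code{focal_strand}, \code{partner_strand},
#'   \code{orientation}, \code{p1}, \code{p2}, \code{ss}, \code{te},
#'   \code{ee}, \code{n_exon_pairs}. The retained focal exon set and the
#'   original focal exon records ride along as attributes (see
#'   [retained_exons()]).
#' @export
intersect_models <- function(focal, partner, mode = c("span", "exon"),
                             te_exclusion = "any_overlap") {
  mode <- match.arg(mode)
  validate_gene_models(focal)
  validate_gene_models(partner)
  if (nrow(focal) == 0 || nrow(partner) == 0) {
    warn("intersect_models: empty focal or partner set; returning no hits")
    return(new_pg_hits(empty_hits_tbl(), focal[0, ], focal[0, ], mode))
  }
  sf <- model_spans(focal) %>%
    select(focal_gene_id = "gene_id", "chrom", focal_start = "start",
           focal_end = "end", focal_strand = "strand",
           focal_n_exons = "n_exons")
  sp <- model_spans(partner) %>%
    select(partner_gene_id = "gene_id", "chrom", partner_start = "start",
           partner_end = "end", partner_strand = "strand",
           partner_n_exons = "n_exons", partner_file_order = "file_order")
  cand <- inner_join(
    sf, sp,
    by = join_by(chrom, overlaps(focal_start, focal_end,
                                 partner_start, partner_end))
  ) %>%
    mutate(
      span_ol = pmin(.data$focal_end, .data$partner_end) -
        pmax(.data$focal_start, .data$partner_start) + 1L,
      p1 = .data$span_ol / interval_length(.data$focal_start, .data$focal_end),
      p2 = .data$span_ol / interval_length(.data$partner_start, .data$partner_end),
      ss = .data$p1 * .data$p2,
      orientation = if_else(.data$focal_strand == .data$partner_strand,
                            "sense", "antisense")
    )

  ef <- distinct_exons(focal) %>%
    semi_join(cand, by = c(gene_id = "focal_gene_id")) %>%
    select(focal_gene_id = "gene_id", "chrom", fe_start = "start",
           fe_end = "end", fe_idx = "exon_idx")
  ep <- distinct_exons(partner) %>%
    semi_join(cand, by = c(gene_id = "partner_gene_id")) %>%
    select(partner_gene_id = "gene_id", "chrom", pe_start = "start",
           pe_end = "end", pe_idx = "exon_idx")
  epairs <- inner_join(
    ef, ep,
    by = join_by(chrom, overlaps(fe_start, fe_end, pe_start, pe_end))
  ) %>%
    mutate(
      ol = pmin(.data$fe_end, .data$pe_end) -
        pmax(.data$fe_start, .data$pe_start) + 1L,
      e = (.data$ol / interval_length(.data$fe_start, .data$fe_end)) *
        (.data$ol / interval_length(.data$pe_start, .data$pe_end)),
      identical_exon = .data$fe_start == .data$pe_start &
        .data$fe_end == .data$pe_end
    )
  agg <- epairs %>%
    group_by(.data$focal_gene_id, .data$partner_gene_id) %>%
    summarise(
      sum_e = sum(.data$e),
      n_exon_pairs = n(),
      matched_partner_exons = dplyr::n_distinct(.data$pe_idx),
      identical_partner_exons = dplyr::n_distinct(.data$pe_idx[.data$identical_exon]),
      .groups = "drop"
    )
  hits <- cand %>%
    left_join(agg, by = c("focal_gene_id", "partner_gene_id")) %>%
    mutate(
      across(c("sum_e"), ~ dplyr::coalesce(.x, 0)),
      across(c("n_exon_pairs", "matched_partner_exons",
               "identical_partner_exons"), ~ dplyr::coalesce(.x, 0L)),
      te = .data$focal_n_exons + .data$partner_n_exons -
        (if (te_exclusion == "any_overlap") .data$matched_partner_exons
         else .data$identical_partner_exons),
      ee = .data$sum_e / .data$te
    )
  if (mode == "exon") hits <- filter(hits, .data$n_exon_pairs > 0)
  hits <- hits %>%
    arrange(.data$chrom, .data$focal_start, .data$focal_gene_id,
            .data$partner_start, .data$partner_gene_id, .data$partner_file_order) %>%
    select("focal_gene_id", "partner_gene_id", "chrom", "focal_start",
           "focal_end", "focal_strand", "partner_strand", "orientation",
           "p1", "p2", "ss", "te", "ee", "n_exon_pairs")

  if (mode == "exon") {
    kept_exons <- epairs %>%
      semi_join(hits, by = c("focal_gene_id", "partner_gene_id")) %>%
      distinct(gene_id = .data$focal_gene_id, .data$chrom,
               start = .data$fe_start, end = .data$fe_end)
  } else {
    kept_exons <- distinct_exons(focal) %>%
      semi_join(hits, by = c(gene_id = "focal_gene_id")) %>%
      select("gene_id", "chrom", "start", "end")
  }
  focal_kept <- focal %>% semi_join(hits, by = c(gene_id = "focal_gene_id"))
  new_pg_hits(hits, kept_exons, focal_kept, mode)
}

empty_hits_tbl <- function() {
  tibble(focal_gene_id = character(), partner_gene_id = character(),
         chrom = character(), focal_start = integer(), focal_end = integer(),
         focal_strand = character(), partner_strand = character(),
         orientation = character(), p1 = double(), p2 = double(),
         ss = double(), te = integer(), ee = double(),
         n_exon_pairs = integer())
}

new_pg_hits <- function(hits, kept_exons, focal_models, mode) {
  structure(as_tibble(hits),
            retained_exons = as_tibble(kept_exons),
            focal_models = as_tibble(focal_models),
            mode = mode,
            class = c("pg_hits", class(as_tibble(hits))))
}

#' Retained exons and models of an intersection result
#'
#' After an exon-mode intersect only the focal exons that matched a partner
#' exon are maintained; these accessors return them, either as a bare exon
#' interval table or reassembled into a gene-model tibble (original records,
#' attributes included) suitable for a further round of intersection.
#'
#' @param hits a \code{pg_hits} result from [intersect_models()] or
#'   [chain_evidence()].
#' @return \code{retained_exons()}: a tibble (\code{gene_id}, \code{chrom},
#'   \code{start}, \code{end}); \code{retained_models()}: a gene-model tibble.
#' @export
retained_exons <- function(hits) {
  attr(hits, "retained_exons") %||%
    abort("not an intersection result (no retained_exons attribute)")
}

#' @rdname retained_exons
#' @export
retained_models <- function(hits) {
  focal <- attr(hits, "focal_models") %||%
    abort("not an intersection result (no focal_models attribute)")
  focal %>%
    semi_join(retained_exons(hits),
              by = c("gene_id", "chrom", "start", "end")) %>%
    arrange(.data$file_order)
}

#' Chain a transcription-evidence set onto anchored loci
#'
#' Takes the pseudogene-by-lncRNA exon-mode result and intersects an evidence
#' set (full-length cDNAs or ESTs) against each locus's retained exons, again
#' requiring exon-to-exon overlap. Evidence orientation is reported relative
#' to the pseudogene. Loci without any evidence partner at the tier are
#' excluded from the tier's output.
#'
#' @param anchored a \code{pg_hits} result (pseudogene x lncRNA, exon mode).
#' @param evidence gene-model tibble of cDNAs or ESTs (ESTs should be
#'   orientation-normalized first; see [normalize_est_orientation()]).
#' @param tier_name label stored on the result, e.g. \code{"cDNA"}.
#' @param te_exclusion see [exon_exon_score()].
#' @return A \code{pg_hits} tibble with a \code{tier} attribute.
#' @export
chain_evidence <- function(anchored, evidence, tier_name = "evidence",
                           te_exclusion = "any_overlap") {
  out <- intersect_models(retained_models(anchored), evidence, mode = "exon",
                          te_exclusion = te_exclusion)
  attr(out, "tier") <- tier_name
  out
}

#' Classify per-locus transcription directionality
#'
#' A locus is \code{"bidirectional"} at an evidence tier when it has at least
#' one sense and at least one antisense supporting partner at that tier,
#' \code{"sense_only"}/\code{"antisense_only"} otherwise.
#'
#' @param hits a \code{pg_hits} tibble for one evidence tier.
#' @param tier tier label recorded in the output (defaults to the tier
#'   attribute set by [chain_evidence()]).
#' @return A tibble: \code{locus_id}, \code{tier}, \code{n_sense},
#'   \code{n_antisense}, \code{call}.
#' @export
classify_directionality <- function(hits, tier = NULL) {
  tier <- tier %||% attr(hits, "tier") %||% "evidence"
  as_tibble(hits) %>%
    group_by(locus_id = .data$focal_gene_id) %>%
    summarise(n_sense = sum(.data$orientation == "sense"),
              n_antisense = sum(.data$orientation == "antisense"),
              .groups = "drop") %>%
    mutate(
      tier = tier,
      call = dplyr::case_when(
        .data$n_sense > 0 & .data$n_antisense > 0 ~ "bidirectional",
        .data$n_sense > 0 ~ "sense_only",
        .data$n_antisense > 0 ~ "antisense_only",
        TRUE ~ "none"
      ),
      .after = "locus_id"
    )
}

#' Combine cDNA and EST directionality calls
#'
#' The combined (cDNA-and-EST) tier keeps loci present in both tiers; a
#' combined call is made only when the same call holds in both tiers
#' independently, otherwise the locus is marked \code{"none"} (discordant).
#' The high-confidence set is the loci called \code{"bidirectional"} in both
#' tiers.
#'
#' @param cdna_calls,est_calls outputs of [classify_directionality()].
#' @return A tibble: \code{locus_id}, \code{tier = "cDNA_and_EST"},
#'   \code{cdna_call}, \code{est_call}, \code{call}, \code{high_confidence}.
#' @export
combine_tier_calls <- function(cdna_calls, est_calls) {
  inner_join(
    cdna_calls %>% select("locus_id", cdna_call = "call"),
    est_calls %>% select("locus_id", est_call = "call"),
    by = "locus_id"
  ) %>%
    mutate(
      tier = "cDNA_and_EST", .after = "locus_id"
    ) %>%
    mutate(
      call = if_else(.data$cdna_call == .data$est_call, .data$cdna_call, "none"),
      high_confidence = .data$call == "bidirectional"
    )
}

#' Run the full chained intersection pipeline
#'
#' For every (pseudogene set, lncRNA set) combination: an exon-mode
#' pseudogene x lncRNA intersect anchors the loci, then the cDNA and EST sets
#' are chained against each locus's retained exons, and per-tier
#' directionality calls are made. EST orientation is normalized from the
#' \code{read_end} attribute unless \code{normalize_ests = FALSE}.
#'
#' @param pseudogenes,lncrnas a gene-model tibble or a named list of them
#'   (one per annotation set).
#' @param cdnas,ests gene-model tibbles of evidence transcripts (optional).
#' @param normalize_ests flip 3' EST strands before chaining (default TRUE).
#' @param te_exclusion see [exon_exon_score()].
#' @return An object of class \code{pg_run}: a list with one element per
#'   combination, each holding \code{pg_set}, \code{lnc_set}, \code{anchored},
#'   \code{tiers} (named list of \code{pg_hits}), \code{calls} (per-tier
#'   directionality tibble) and \code{combined} (see [combine_tier_calls()]).
#' @export
run_intersections <- function(pseudogenes, lncrnas, cdnas = NULL, ests = NULL,
                              normalize_ests = TRUE,
                              te_exclusion = "any_overlap") {
  pg_sets <- as_set_list(pseudogenes, "pseudogenes")
  lnc_sets <- as_set_list(lncrnas, "lncrnas")
  if (!is.null(ests) && normalize_ests) ests <- normalize_est_orientation(ests)
  combos <- purrr::map(names(pg_sets), function(pg_name) {
    purrr::map(names(lnc_sets), function(lnc_name) {
      anchored <- intersect_models(pg_sets[[pg_name]], lnc_sets[[lnc_name]],
                                   mode = "exon", te_exclusion = te_exclusion)
      tiers <- list()
      calls <- list()
      if (!is.null(cdnas) && nrow(anchored) > 0) {
        tiers$cDNA <- chain_evidence(anchored, cdnas, "cDNA", te_exclusion)
        calls$cDNA <- classify_directionality(tiers$cDNA)
      }
      if (!is.null(ests) && nrow(anchored) > 0) {
        tiers$EST <- chain_evidence(anchored, ests, "EST", te_exclusion)
        calls$EST <- classify_directionality(tiers$EST)
      }
      combined <- if (all(c("cDNA", "EST") %in% names(calls))) {
        combine_tier_calls(calls$cDNA, calls$EST)
      }
      list(pg_set = pg_name, lnc_set = lnc_name, anchored = anchored,
           tiers = tiers, calls = calls, combined = combined)
    })
  }) %>% purrr::flatten()
  structure(combos, class = "pg_run")
}

as_set_list <- function(x, what) {
  if (is.data.frame(x)) {
    nm <- unique(x$source)
    if (length(nm) == 1) return(stats::setNames(list(x), nm))
    return(split(x, x$source))
  }
  if (is.list(x)) {
    if (is.null(names(x)) || any(names(x) == "")) {
      abort(paste0(what, ": a list of annotation sets must be named"))
    }
    return(x)
  }
  abort(paste0(what, " must be a gene-model tibble or a named list of them"))
}

orientation_breakdown <- function(hits) {
  per_locus <- as_tibble(hits) %>%
    group_by(.data$focal_gene_id) %>%
    summarise(has_sense = any(.data$orientation == "sense"),
              has_antisense = any(.data$orientation == "antisense"),
              .groups = "drop")
  tibble(
    exon_exon_gene_ids = nrow(per_locus),
    sense_overlaps = sum(per_locus$has_sense & !per_locus$has_antisense),
    antisense_overlaps = sum(per_locus$has_antisense & !per_locus$has_sense),
    complex_loci = sum(per_locus$has_sense & per_locus$has_antisense)
  )
}

#' Summarize a pipeline run
#'
#' One row per (pseudogene set, lncRNA set) combination and per evidence tier,
#' with the locus counts partitioned by partner orientation: "sense overlaps"
#' are loci whose partners at the row's level are all sense relative to the
#' pseudogene, "antisense overlaps" all antisense, and "complex loci" have
#' partners in both orientations; the three always sum to the gene-id total.
#' The combined (cDNA and EST) row counts loci present in both tiers, with
#' orientation taken over the union of their evidence partners.
#'
#' @param run a \code{pg_run} from [run_intersections()].
#' @return A tibble: \code{file1}, \code{file2}, \code{exon_exon_gene_ids},
#'   \code{sense_overlaps}, \code{antisense_overlaps}, \code{complex_loci}.
#' @export
intersect_summary <- function(run) {
  stopifnot(inherits(run, "pg_run"))
  out <- purrr::map(run, function(cb) {
    rows <- list(
      dplyr::bind_cols(tibble(file1 = cb$pg_set, file2 = cb$lnc_set),
                       orientation_breakdown(cb$anchored))
    )
    vs <- paste(cb$pg_set, "vs.", cb$lnc_set)
    for (tier in names(cb$tiers)) {
      rows <- c(rows, list(dplyr::bind_cols(
        tibble(file1 = vs, file2 = tier),
        orientation_breakdown(cb$tiers[[tier]])
      )))
    }
    if (!is.null(cb$combined) && length(cb$tiers) == 2) {
      both <- dplyr::bind_rows(as_tibble(cb$tiers$cDNA),
                               as_tibble(cb$tiers$EST)) %>%
        semi_join(cb$combined, by = c(focal_gene_id = "locus_id"))
      rows <- c(rows, list(dplyr::bind_cols(
        tibble(file1 = vs, file2 = "cDNA and EST"),
        orientation_breakdown(both)
      )))
    }
    bind_rows(rows)
  }) %>% bind_rows()
  structure(out, class = c("pg_summary", class(out)))
}

#' Directionality matrix across evidence tiers
#'
#' Counts loci by directionality call for the cDNA tier, the EST tier, and
#' the combined tier, over the loci that have evidence in both tiers (the
#' high-confidence candidate universe). In the combined row a locus is
#' counted only when the same call holds in both tiers.
#'
#' @param run a \code{pg_run} from [run_intersections()] whose combinations
#'   carry both cDNA and EST tiers.
#' @return A tibble with columns \code{support_from}, \code{bidirectional},
#'   \code{antisense_only}, \code{sense_only}.
#' @export
directionality_matrix <- function(run) {
  stopifnot(inherits(run, "pg_run"))
  combined <- purrr::map(run, function(cb) {
    if (is.null(cb$combined)) return(NULL)
    cb$combined %>%
      mutate(pg_set = cb$pg_set, lnc_set = cb$lnc_set)
  }) %>% purrr::compact() %>% bind_rows()
  if (nrow(combined) == 0) {
    abort("directionality_matrix needs a run with both cDNA and EST tiers")
  }
  count_calls <- function(calls) {
    tibble(bidirectional = sum(calls == "bidirectional"),
           antisense_only = sum(calls == "antisense_only"),
           sense_only = sum(calls == "sense_only"))
  }
  bind_rows(
    dplyr::bind_cols(tibble(support_from = "cDNA"),
                     count_calls(combined$cdna_call)),
    dplyr::bind_cols(tibble(support_from = "EST"),
                     count_calls(combined$est_call)),
    dplyr::bind_cols(tibble(support_from = "EST and cDNA"),
                     count_calls(combined$call))
  )
}

#' Write loci with their partner annotations as GTF
#'
#' One line per focal pseudogene gene id, spanning the gene and preserving its
#' original attribute block, with every partner appended as a parenthesized
#' group \code{(partnerID:SS:orientation:EE)} in input order; SS and EE are
#' rounded to 4 decimals. The file re-parses under [read_gtf()].
#'
#' @param hits a \code{pg_hits} tibble.
#' @param path output file path.
#' @param digits decimals for SS/EE serialization (default 4).
#' @return \code{path}, invisibly.
#' @examples
#' \dontrun{
#' write_annotated_gtf(hits, "hits.gtf")
#' }
#' @export
write_annotated_gtf <- function(hits, path, digits = 4) {
  focal <- attr(hits, "focal_models") %||%
    abort("not an intersection result (no focal_models attribute)")
  fmt <- paste0("(%s:%.", digits, "f:%s:%.", digits, "f)")
  per_locus <- as_tibble(hits) %>%
    mutate(group = sprintf(fmt, .data$partner_gene_id, .data$ss,
                           .data$orientation, .data$ee)) %>%
    group_by(.data$focal_gene_id, .data$chrom, .data$focal_start,
             .data$focal_end, .data$focal_strand) %>%
    summarise(groups = paste(.data$group, collapse = " "), .groups = "drop")
  meta <- focal %>%
    group_by(.data$gene_id) %>%
    summarise(source = first(.data$source), attributes = first(.data$attributes),
              .groups = "drop")
  out <- per_locus %>%
    left_join(meta, by = c(focal_gene_id = "gene_id")) %>%
    arrange(.data$chrom, .data$focal_start, .data$focal_gene_id)
  lines <- sprintf("%s\t%s\texon\t%d\t%d\t.\t%s\t.\t%s %s",
                   out$chrom, out$source, out$focal_start, out$focal_end,
                   out$focal_strand, out$attributes, out$groups)
  readr::write_lines(lines, path)
  invisible(path)
}
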