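#' Specify a synthetic fixture set
#'
#' Describes a small, fully determined input ecosystem on a toy genome: a
#' pseudogene catalog with planted lncRNA overlaps, full-length cDNA and EST
#' evidence with chosen per-tier directionality, piRNAs placed exonic or
#' intronic, disease SNPs placed inside/at/beyond the proximity window, and
#' two further pseudogene catalogs with controlled accession synonymy for
#' merge tests. [generate_fixture()] materializes it and returns the planted
#' truth alongside.
#'
#' Per-locus directives (`loci` tibble, one row per planted pseudogene):
#' \describe{
#'   \item{lnc}{\code{"sense"}, \code{"antisense"}, \code{"both"} (one lncRNA
#'     partner per orientation), \code{"span_only"} (lncRNA inside an intron:
#'     span overlap, no exon overlap) or \code{"none"}.}
#'   \item{cdna, est}{evidence tier directionality: \code{"none"},
#'     \code{"sense_only"}, \code{"antisense_only"}, \code{"bidirectional"}
#'     (strands relative to the pseudogene).}
#'   \item{pirna}{\code{"exonic"} (overlaps a retained exon),
#'     \code{"intronic"} (inside the locus but touching no exon) or
#'     \code{"none"}.}
#'   \item{snp}{\code{"inside"} (within the span), \code{"edge"} (exactly
#'     \code{snp_window} bp past the span end), \code{"outside"} (one base
#'     beyond that) or \code{"none"}.}
#' }
#' Evidence, piRNA and SNP directives require an exon-anchored locus
#' (\code{lnc} of sense/antisense/both); requesting them on an unanchored
#' locus is a spec error.
#'
#' @param loci directive tibble as above; default
#'   [default_locus_directives()].
#' @param n_decoy_lnc lncRNAs placed far from every pseudogene.
#' @param n_unique_b,n_unique_c loci private to the second/third pseudogene
#'   catalog (for merge/Venn tests).
#' @param prop_3prime_est fraction of EST records tagged as 3' reads; those
#'   are emitted on the strand opposite their biological direction, as GenBank
#'   convention has it, so orientation normalization is causally exercised.
#' @param snp_window SNP proximity window the truth is computed for (bp).
#' @param chroms toy chromosome names.
#' @param window_bp per-locus window; loci are spaced this far apart so
#'   planted structures cannot cross-talk (must exceed gene span + 2 *
#'   \code{snp_window}).
#' @return A \code{fixture_spec} list.
#' @export
fixture_spec <- function(loci = default_locus_directives(),
                         n_decoy_lnc = 2, n_unique_b = 2, n_unique_c = 2,
                         prop_3prime_est = 0.5, snp_window = 10000,
                         chroms = c("chr1", "chr2", "chr3"),
                         window_bp = 30000) {
  loci <- as_tibble(loci)
  need <- c("lnc", "cdna", "est", "pirna", "snp")
  if (!all(need %in% names(loci))) {
    abort(paste0("locus directives need columns: ", paste(need, collapse = ", ")))
  }
  ok <- list(lnc = c("sense", "antisense", "both", "span_only", "none"),
             cdna = c("none", "sense_only", "antisense_only", "bidirectional"),
             est = c("none", "sense_only", "antisense_only", "bidirectional"),
             pirna = c("exonic", "intronic", "none"),
             snp = c("inside", "edge", "outside", "none"))
  for (col in need) {
    bad <- setdiff(unique(loci[[col]]), ok[[col]])
    if (length(bad) > 0) {
      abort(sprintf("invalid %s directive: %s", col, bad[1]))
    }
  }
  unanchored <- !loci$lnc %in% c("sense", "antisense", "both")
  conflicted <- unanchored &
    (loci$cdna != "none" | loci$est != "none" | loci$pirna != "none" |
       loci$snp != "none")
  if (any(conflicted)) {
    abort(sprintf(paste0("locus %d: evidence/piRNA/SNP directives require an ",
                         "exon-anchored lncRNA partner (lnc = sense/antisense/both)"),
                  which(conflicted)[1]))
  }
  if (window_bp < 6000 + 2 * snp_window) {
    abort("window_bp too small for the requested snp_window")
  }
  structure(list(loci = loci, n_decoy_lnc = n_decoy_lnc,
                 n_unique_b = n_unique_b, n_unique_c = n_unique_c,
                 prop_3prime_est = prop_3prime_est, snp_window = snp_window,
                 chroms = chroms, window_bp = window_bp),
            class = "fixture_spec")
}

#' @rdname fixture_spec
#' @export
default_locus_directives <- function() {
  tibble::tribble(
    ~lnc,        ~cdna,            ~est,             ~pirna,     ~snp,
    "sense",     "sense_only",     "sense_only",     "exonic",   "inside",
    "sense",     "bidirectional",  "bidirectional",  "intronic", "edge",
    "antisense", "antisense_only", "antisense_only", "none",     "outside",
    "both",      "bidirectional",  "bidirectional",  "exonic",   "none",
    "sense",     "none",           "sense_only",     "none",     "none",
    "both",      "sense_only",     "bidirectional",  "exonic",   "none",
    "antisense", "bidirectional",  "bidirectional",  "none",     "inside",
    "none",      "none",           "none",           "none",     "none",
    "sense",     "bidirectional",  "sense_only",     "intronic", "none",
    "both",      "none",           "none",           "exonic",   "edge",
    "span_only", "none",           "none",           "none",     "none",
    "antisense", "antisense_only", "bidirectional",  "none",     "none"
  )
}

flip_strand <- function(s) if_else(s == "+", "-", "+")

#' Generate fixture files and their planted truth table
#'
#' Emits, under \code{dir}: three pseudogene catalog GTFs (\code{pgA} holds
#' every planted locus; \code{pgB}/\code{pgC} hold coordinate-jittered
#' accession synonyms per the membership cycle plus their private loci), a
#' lncRNA GTF, a cDNA GTF, an EST GTF with \code{read_end} attributes, a
#' piRNA BED, a SNP TSV and three truth TSVs. Byte-identical output for the
#' same spec and seed.
#'
#' @param spec a [fixture_spec()].
#' @param dir output directory (created if needed).
#' @param seed integer seed controlling all randomness.
#' @return A list: \code{paths} (named file paths), \code{models} (the
#'   in-memory gene-model/feature tibbles) and \code{truth} with elements
#'   \code{loci} (per-locus expectations: lncRNA category, per-tier calls,
#'   combined call, high-confidence flag, piRNA support, SNP hit),
#'   \code{partners} (per planted pseudogene-lncRNA pair: expected P1, P2,
#'   SS, TE, EE, orientation) and \code{venn} (expected merge cells and
#'   per-source non-redundant counts).
#' @examples
#' fx <- generate_fixture(fixture_spec(), tempfile("fx"), seed = 7)
#' fx$truth$loci
#' @export
generate_fixture <- function(spec, dir, seed = 1) {
  stopifnot(inherits(spec, "fixture_spec"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  withr::with_seed(as.integer(seed), generate_fixture_impl(spec, dir))
}

generate_fixture_impl <- function(spec, dir) {
  loci <- spec$loci
  n_loci <- nrow(loci)
  nc <- length(spec$chroms)
  window_of <- function(w) { # 0-based global window index -> (chrom, base)
    list(chrom = spec$chroms[(w %% nc) + 1],
         base = (w %/% nc) * spec$window_bp + sample(500:2500, 1))
  }
  membership_cycle <- list("A", c("A", "B"), c("A", "B", "C"), c("A", "C"))

  pg_rows <- list(); lnc_rows <- list(); cdna_rows <- list(); est_rows <- list()
  pirna_rows <- list(); snp_rows <- list()
  truth_loci <- list(); truth_partners <- list()
  catalog_membership <- character(n_loci)
  lnc_n <- 0; ev_n <- 0

  mk_exon_rows <- function(src, gid, chrom, starts, ends, strand,
                           extra_attr = "") {
    tibble(source = src, chrom = chrom, start = as.integer(starts),
           end = as.integer(ends), strand = strand, gene_id = gid,
           transcript_id = paste0(gid, ".1"),
           attributes = sprintf('gene_id "%s"; transcript_id "%s.1";%s',
                                gid, gid, extra_attr))
  }

  for (i in seq_len(n_loci)) {
    d <- loci[i, ]
    w <- window_of(i - 1)
    needs_intron <- d$lnc == "span_only" || d$pirna == "intronic"
    n_ex <- if (needs_intron) sample(2:5, 1) else sample(1:5, 1)
    exon_len <- sample(100:400, n_ex, replace = TRUE)
    intron_len <- if (n_ex > 1) sample(200:800, n_ex - 1, replace = TRUE) else integer()
    starts <- w$base + cumsum(c(0L, head(exon_len, -1) + intron_len))
    ends <- starts + exon_len - 1L
    strand <- sample(c("+", "-"), 1)
    gid <- sprintf("PG%03d", i)
    pg_rows[[i]] <- mk_exon_rows("pgA", gid, w$chrom, starts, ends, strand)
    catalog_membership[i] <- paste(membership_cycle[[((i - 1) %% 4) + 1]],
                                   collapse = "+")
    span <- c(starts[1], ends[n_ex])

    # lncRNA partners: single-exon genes half-covering one pseudogene exon
    k1 <- sample(n_ex, 1)
    k2 <- if (n_ex > 1) sample(setdiff(seq_len(n_ex), k1), 1) else k1
    plant_lnc <- function(k, orient) {
      lnc_n <<- lnc_n + 1
      lid <- sprintf("LNC%03d", lnc_n)
      l_start <- starts[k] + exon_len[k] %/% 2L
      max_end <- if (k < n_ex) starts[k + 1] - 50L else ends[k] + 2000L
      l_end <- min(ends[k] + sample(50:300, 1), max_end)
      l_strand <- if (orient == "sense") strand else flip_strand(strand)
      lnc_rows[[length(lnc_rows) + 1]] <<-
        mk_exon_rows("lnc", lid, w$chrom, l_start, l_end, l_strand)
      ol_ex <- ends[k] - l_start + 1L
      e_pair <- (ol_ex / exon_len[k]) * (ol_ex / (l_end - l_start + 1L))
      ol_span <- min(span[2], l_end) - max(span[1], l_start) + 1L
      p1 <- ol_span / (span[2] - span[1] + 1L)
      p2 <- ol_span / (l_end - l_start + 1L)
      truth_partners[[length(truth_partners) + 1]] <<- tibble(
        locus_id = gid, partner_id = lid, orientation = orient,
        target_exon = k, p1 = p1, p2 = p2, ss = p1 * p2,
        te = n_ex, ee = e_pair / n_ex
      )
      k
    }
    retained <- integer()
    if (d$lnc == "sense") retained <- plant_lnc(k1, "sense")
    if (d$lnc == "antisense") retained <- plant_lnc(k1, "antisense")
    if (d$lnc == "both") {
      retained <- c(plant_lnc(k1, "sense"), plant_lnc(k2, "antisense"))
    }
    if (d$lnc == "span_only") {
      lnc_n <- lnc_n + 1
      gap <- starts[2] - ends[1] - 1L
      l_start <- ends[1] + 20L
      l_end <- l_start + min(gap - 40L, sample(60:150, 1))
      lnc_rows[[length(lnc_rows) + 1]] <-
        mk_exon_rows("lnc", sprintf("LNC%03d", lnc_n), w$chrom,
                     l_start, l_end, sample(c("+", "-"), 1))
    }

    # evidence transcripts: single-exon genes covering the left half of a
    # retained exon (plus flank), on the strand the tier directive asks for
    plant_evidence <- function(call, tier) {
      if (call == "none") return(invisible())
      orients <- switch(call, sense_only = "sense",
                        antisense_only = "antisense",
                        bidirectional = c("sense", "antisense"))
      for (orient in orients) {
        ev_n <<- ev_n + 1
        k <- retained[1]
        ev_start <- max(1L, starts[k] - sample(50:150, 1))
        ev_end <- starts[k] + exon_len[k] %/% 2L
        bio_strand <- if (orient == "sense") strand else flip_strand(strand)
        if (tier == "cDNA") {
          cdna_rows[[length(cdna_rows) + 1]] <<-
            mk_exon_rows("cdna", sprintf("CDNA%03d", ev_n), w$chrom,
                         ev_start, ev_end, bio_strand)
        } else {
          is_3p <- runif(1) < spec$prop_3prime_est
          emitted <- if (is_3p) flip_strand(bio_strand) else bio_strand
          est_rows[[length(est_rows) + 1]] <<-
            mk_exon_rows("est", sprintf("EST%03d", ev_n), w$chrom,
                         ev_start, ev_end, emitted,
                         sprintf(' read_end "%s";',
                                 if (is_3p) "3prime" else "5prime"))
        }
      }
    }
    plant_evidence(d$cdna, "cDNA")
    plant_evidence(d$est, "EST")

    # piRNA placement
    pirna_count <- 0L
    if (d$pirna == "exonic") {
      k <- retained[1]
      pirna_rows[[length(pirna_rows) + 1]] <- tibble(
        chrom = w$chrom, start0 = starts[k] + 9L, end0 = starts[k] + 30L,
        id = sprintf("pi_%s", gid))
      pirna_count <- 1L
    } else if (d$pirna == "intronic") {
      pirna_rows[[length(pirna_rows) + 1]] <- tibble(
        chrom = w$chrom, start0 = ends[1] + 19L, end0 = ends[1] + 45L,
        id = sprintf("pi_%s", gid))
    }

    # SNP placement relative to the span
    if (d$snp != "none") {
      pos <- switch(d$snp,
                    inside = (span[1] + span[2]) %/% 2L,
                    edge = span[2] + as.integer(spec$snp_window),
                    outside = span[2] + as.integer(spec$snp_window) + 1L)
      snp_rows[[length(snp_rows) + 1]] <- tibble(
        rsid = sprintf("rs%04d", i), chrom = w$chrom, pos = as.integer(pos),
        trait = sprintf("trait_%d", i))
    }

    anchored <- d$lnc %in% c("sense", "antisense", "both")
    combined <- if (d$cdna == "none" || d$est == "none") NA_character_ else {
      cd <- d$cdna; es <- d$est
      if (cd == es) cd else "none"
    }
    truth_loci[[i]] <- tibble(
      locus_id = gid, chrom = w$chrom, strand = strand,
      span_start = span[1], span_end = span[2], n_exons = n_ex,
      lnc_category = switch(d$lnc, sense = "sense", antisense = "antisense",
                            both = "complex", span_only = "span_only",
                            none = "none"),
      anchored = anchored,
      cdna_call = if (d$cdna == "none") NA_character_ else d$cdna,
      est_call = if (d$est == "none") NA_character_ else d$est,
      combined_call = combined,
      high_confidence = identical(combined, "bidirectional"),
      pirna_supported = d$pirna == "exonic",
      pirna_count = pirna_count,
      snp_directive = d$snp,
      snp_hit = d$snp %in% c("inside", "edge"),
      snp_inside = d$snp == "inside"
    )
  }

  # synonym catalogs B and C: jittered copies per the membership cycle,
  # plus private loci in fresh windows
  w_next <- n_loci
  mk_catalog <- function(tag, n_unique) {
    rows <- list()
    for (i in seq_len(n_loci)) {
      if (!grepl(tag, catalog_membership[i], fixed = TRUE)) next
      src_rows <- pg_rows[[i]]
      jitter <- sample(-40:40, 1)
      rows[[length(rows) + 1]] <- src_rows %>%
        mutate(source = paste0("pg", tag),
               start = .data$start + jitter, end = .data$end + jitter,
               gene_id = paste0(tag, "_", .data$gene_id),
               transcript_id = paste0(tag, "_", .data$transcript_id),
               attributes = sprintf('gene_id "%s"; transcript_id "%s";',
                                    .data$gene_id, .data$transcript_id))
    }
    for (j in seq_len(n_unique)) {
      w <- window_of(w_next)
      w_next <<- w_next + 1
      len <- sample(300:1500, 1)
      rows[[length(rows) + 1]] <- mk_exon_rows(
        paste0("pg", tag), sprintf("%s_UNIQ%02d", tag, j), w$chrom,
        w$base, w$base + len, sample(c("+", "-"), 1))
    }
    bind_rows(rows)
  }
  pg_b <- mk_catalog("B", spec$n_unique_b)
  pg_c <- mk_catalog("C", spec$n_unique_c)

  # decoy lncRNAs far from everything
  for (j in seq_len(spec$n_decoy_lnc)) {
    w <- window_of(w_next)
    w_next <- w_next + 1
    lnc_n <- lnc_n + 1
    len <- sample(200:900, 1)
    lnc_rows[[length(lnc_rows) + 1]] <-
      mk_exon_rows("lnc", sprintf("LNC%03d", lnc_n), w$chrom,
                   w$base, w$base + len, sample(c("+", "-"), 1))
  }

  finalize <- function(rows) {
    combined <- bind_rows(rows)
    if (nrow(combined) == 0) {
      return(gene_models(source = character(), chrom = character(),
                         start = integer(), end = integer(),
                         strand = character(), gene_id = character()))
    }
    combined %>% mutate(file_order = row_number()) %>%
      validate_gene_models()
  }
  models <- list(
    pseudogenes_a = finalize(pg_rows),
    pseudogenes_b = finalize(list(pg_b)),
    pseudogenes_c = finalize(list(pg_c)),
    lncrnas = finalize(lnc_rows),
    cdnas = finalize(cdna_rows),
    ests = finalize(est_rows)
  )
  pirnas <- bind_rows(pirna_rows)
  snps <- bind_rows(snp_rows)

  # expected merge/Venn cells
  cell_counts <- table(catalog_membership)
  venn <- bind_rows(
    tibble(cell = names(cell_counts), n_loci = as.integer(cell_counts)),
    tibble(cell = "B", n_loci = spec$n_unique_b),
    tibble(cell = "C", n_loci = spec$n_unique_c)
  ) %>%
    filter(.data$n_loci > 0) %>%
    group_by(.data$cell) %>% summarise(n_loci = sum(.data$n_loci), .groups = "drop")
  per_source <- tibble(
    source = c("A", "B", "C"),
    n_loci = c(n_loci,
               sum(grepl("B", catalog_membership)) + spec$n_unique_b,
               sum(grepl("C", catalog_membership)) + spec$n_unique_c)
  )
  truth <- list(
    loci = bind_rows(truth_loci),
    partners = bind_rows(truth_partners),
    venn = venn,
    per_source = per_source,
    merged_count = n_loci + spec$n_unique_b + spec$n_unique_c
  )

  paths <- c(
    pseudogenes_a = file.path(dir, "pseudogenes_A.gtf"),
    pseudogenes_b = file.path(dir, "pseudogenes_B.gtf"),
    pseudogenes_c = file.path(dir, "pseudogenes_C.gtf"),
    lncrnas = file.path(dir, "lncrnas.gtf"),
    cdnas = file.path(dir, "cdnas.gtf"),
    ests = file.path(dir, "ests.gtf"),
    pirnas = file.path(dir, "pirnas.bed"),
    snps = file.path(dir, "snps.tsv"),
    truth_loci = file.path(dir, "truth_loci.tsv"),
    truth_partners = file.path(dir, "truth_partners.tsv"),
    truth_venn = file.path(dir, "truth_venn.tsv")
  )
  for (nm in names(models)) write_gtf(models[[nm]], paths[[nm]])
  if (nrow(pirnas) > 0) {
    readr::write_lines(sprintf("%s\t%d\t%d\t%s", pirnas$chrom, pirnas$start0,
                               pirnas$end0, pirnas$id), paths[["pirnas"]])
  } else {
    readr::write_lines(character(), paths[["pirnas"]])
  }
  readr::write_lines(
    c("rsid\tchrom\tpos\ttrait",
      if (nrow(snps) > 0) sprintf("%s\t%s\t%d\t%s", snps$rsid, snps$chrom,
                                  snps$pos, snps$trait)),
    paths[["snps"]])
  readr::write_tsv(truth$loci, paths[["truth_loci"]], progress = FALSE)
  readr::write_tsv(truth$partners, paths[["truth_partners"]], progress = FALSE)
  readr::write_tsv(truth$venn, paths[["truth_venn"]], progress = FALSE)

  list(paths = paths, models = models, truth = truth, spec = spec)
}

#' Random gene models for property tests
#'
#' Draws \code{n_genes} multi-exon gene models with unconstrained positions
#' (overlaps between genes are allowed and likely) on a toy genome. Uses the
#' current RNG state; seed outside for reproducibility.
#'
#' @param n_genes number of genes.
#' @param chroms chromosome names to draw from.
#' @param max_pos maximum exon end coordinate.
#' @param source_tag source tag for the generated set.
#' @param id_prefix prefix for generated gene ids.
#' @return A gene-model tibble.
#' @export
random_gene_models <- function(n_genes, chroms = c("chr1", "chr2"),
                               max_pos = 50000, source_tag = "rand",
                               id_prefix = "G") {
  rows <- purrr::map(seq_len(n_genes), function(i) {
    n_ex <- sample(1:5, 1)
    exon_len <- sample(30:300, n_ex, replace = TRUE)
    intron_len <- if (n_ex > 1) sample(20:500, n_ex - 1, replace = TRUE) else integer()
    base <- sample(seq_len(max_pos), 1)
    starts <- base + cumsum(c(0L, head(exon_len, -1) + intron_len))
    tibble(source = source_tag, chrom = sample(chroms, 1),
           start = as.integer(starts), end = as.integer(starts + exon_len - 1L),
           strand = sample(c("+", "-"), 1),
           gene_id = sprintf("%s%04d", id_prefix, i),
           transcript_id = sprintf("%s%04d.1", id_prefix, i))
  })
  bind_rows(rows) %>%
    mutate(attributes = sprintf('gene_id "%s"; transcript_id "%s";',
                                .data$gene_id, .data$transcript_id),
           file_order = row_number()) %>%
    validate_gene_models()
}
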