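#' piRNA exonic-overlap support per locus
#'
#' A locus is piRNA-supported when at least one of its (retained) exons shares
#' at least one base with at least one piRNA interval; piRNAs falling inside
#' the span but wholly intronic do not count. \code{pirna_count} is the number
#' of distinct piRNA ids touching the locus's exons.
#'
#' @param exons exon intervals per locus: a tibble with columns
#'   \code{gene_id}, \code{chrom}, \code{start}, \code{end} (e.g.
#'   [retained_exons()] of a pipeline result, or [distinct_exons()]).
#' @param pirnas piRNA features as read by [read_point_features()] (columns
#'   \code{id}, \code{chrom}, \code{start}, \code{end}).
#' @return A tibble with one row per locus: \code{locus_id},
#'   \code{supported}, \code{pirna_count}, \code{pirna_ids} (comma-joined).
#'   The aggregate counts are available via [pirna_summary()].
#' @export
pirna_support <- function(exons, pirnas) {
  stopifnot(all(c("gene_id", "chrom", "start", "end") %in% names(exons)),
            all(c("id", "chrom", "start", "end") %in% names(pirnas)))
  hits <- inner_join(
    exons %>% select(locus_id = "gene_id", "chrom", es = "start", ee = "end"),
    pirnas %>% select(pirna_id = "id", "chrom", ps = "start", pe = "end"),
    by = join_by(chrom, overlaps(es, ee, ps, pe))
  )
  per_locus <- hits %>%
    group_by(.data$locus_id) %>%
    summarise(pirna_count = dplyr::n_distinct(.data$pirna_id),
              pirna_ids = paste(sort(unique(.data$pirna_id)), collapse = ","),
              .groups = "drop")
  exons %>%
    distinct(locus_id = .data$gene_id) %>%
    left_join(per_locus, by = "locus_id") %>%
    mutate(pirna_count = dplyr::coalesce(.data$pirna_count, 0L),
           pirna_ids = dplyr::coalesce(.data$pirna_ids, ""),
           supported = .data$pirna_count >= 1L) %>%
    relocate("locus_id", "supported", "pirna_count", "pirna_ids")
}

#' @rdname pirna_support
#' @param support output of [pirna_support()].
#' @return \code{pirna_summary()}: a one-row tibble with \code{n_loci},
#'   \code{n_supported}, \code{pct_supported} (2 decimals, half-up) and
#'   \code{mean_pirnas_per_supported_locus} (mean over supported loci only).
#' @export
pirna_summary <- function(support) {
  n_sup <- sum(support$supported)
  tibble(
    n_loci = nrow(support),
    n_supported = n_sup,
    pct_supported = proportion_percent(n_sup, max(nrow(support), 1L)),
    mean_pirnas_per_supported_locus =
      if (n_sup > 0) mean(support$pirna_count[support$supported]) else NA_real_
  )
}

#' Disease-SNP proximity to locus spans
#'
#' A SNP hits a locus when its position lies within the gene span extended by
#' \code{window} bases on either end, boundaries inclusive: a SNP exactly
#' \code{window} bases past an end is still a hit, one base further is not.
#' SNPs inside the span proper are flagged and get distance 0; otherwise the
#' distance to the nearest span end is reported.
#'
#' @param loci locus spans: a gene-model tibble (spans are derived with
#'   [model_spans()]) or a tibble already carrying one row per locus with
#'   \code{gene_id}, \code{chrom}, \code{start}, \code{end}.
#' @param snps SNP features as read by [read_point_features()] (columns
#'   \code{id}, \code{chrom}, \code{position}, \code{payload}).
#' @param window flanking window in bp (default 10000).
#' @return A tibble of hits: \code{locus_id}, \code{rsid}, \code{chrom},
#'   \code{position}, \code{distance}, \code{inside_span}, \code{trait}.
#' @export
snp_proximity <- function(loci, snps, window = 10000) {
  stopifnot(window >= 0)
  spans <- if (all(model_columns %in% names(loci))) model_spans(loci) else loci
  stopifnot(all(c("gene_id", "chrom", "start", "end") %in% names(spans)))
  spans <- spans %>%
    select(locus_id = "gene_id", "chrom", span_start = "start",
           span_end = "end") %>%
    mutate(w_start = .data$span_start - as.integer(window),
           w_end = .data$span_end + as.integer(window))
  pts <- snps %>%
    select(rsid = "id", "chrom", "position", trait = "payload")
  inner_join(spans, pts,
             by = join_by(chrom, between(y$position, x$w_start, x$w_end))) %>%
    mutate(
      inside_span = .data$position >= .data$span_start &
        .data$position <= .data$span_end,
      distance = dplyr::case_when(
        inside_span ~ 0L,
        .data$position < .data$span_start ~ .data$span_start - .data$position,
        TRUE ~ .data$position - .data$span_end
      )
    ) %>%
    select("locus_id", "rsid", "chrom", "position", "distance",
           "inside_span", "trait") %>%
    arrange(.data$chrom, .data$position, .data$locus_id)
}

#' Pooled two-proportion z-test (one-tailed)
#'
#' Compares two observed proportions \code{x1/n1} and \code{x2/n2} with the
#' pooled-variance normal approximation, without continuity correction:
#' \deqn{z = (p1 - p2) / \sqrt{\hat p (1 - \hat p)(1/n1 + 1/n2)}}
#' with pooled \eqn{\hat p = (x1 + x2)/(n1 + n2)}. The one-tailed p-value is
#' the standard normal tail in the declared direction (\code{"less"}: lower
#' tail, \code{"greater"}: upper tail).
#'
#' @param x1,n1,x2,n2 successes and totals per group (\code{0 <= x <= n},
#'   \code{n >= 1}).
#' @param direction alternative hypothesis: is group 1's proportion
#'   \code{"less"} or \code{"greater"} than group 2's?
#' @return An object of class \code{prop_ztest} with fields \code{x1},
#'   \code{n1}, \code{x2}, \code{n2}, \code{p1_hat}, \code{p2_hat},
#'   \code{p_pooled}, \code{z}, \code{p_one_tailed}, \code{direction}.
#'   \code{z} and \code{p_one_tailed} are \code{NA} when the pooled
#'   proportion is 0 or 1 (degenerate variance). [tidy()] and [glance()]
#'   methods are provided.
#' @examples
#' two_proportion_ztest(367, 1167, 109, 313, direction = "less")
#' @export
two_proportion_ztest <- function(x1, n1, x2, n2,
                                 direction = c("less", "greater")) {
  direction <- match.arg(direction)
  if (n1 < 1 || n2 < 1) abort("both group sizes must be >= 1")
  if (x1 < 0 || x1 > n1 || x2 < 0 || x2 > n2) {
    abort("counts must satisfy 0 <= x <= n in both groups")
  }
  p1 <- x1 / n1
  p2 <- x2 / n2
  pp <- (x1 + x2) / (n1 + n2)
  if (pp %in% c(0, 1)) {
    warn("pooled proportion is 0 or 1; z is undefined")
    z <- NA_real_
    p <- NA_real_
  } else {
    z <- (p1 - p2) / sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
    p <- if (direction == "less") pnorm(z) else pnorm(z, lower.tail = FALSE)
  }
  structure(
    list(x1 = x1, n1 = n1, x2 = x2, n2 = n2, p1_hat = p1, p2_hat = p2,
         p_pooled = pp, z = z, p_one_tailed = p, direction = direction),
    class = "prop_ztest"
  )
}

#' @export
print.prop_ztest <- function(x, ...) {
  cat("Two-proportion z-test (pooled, one-tailed)\n")
  cat(sprintf("  group 1: %d / %d (%.2f%%)\n", x$x1, x$n1, 100 * x$p1_hat))
  cat(sprintf("  group 2: %d / %d (%.2f%%)\n", x$x2, x$n2, 100 * x$p2_hat))
  cat(sprintf("  z = %.4f, one-tailed p (%s) = %.5f\n",
              x$z, x$direction, x$p_one_tailed))
  invisible(x)
}

#' @method tidy prop_ztest
#' @export
tidy.prop_ztest <- function(x, ...) {
  tibble(estimate1 = x$p1_hat, estimate2 = x$p2_hat,
         statistic = x$z, p.value = x$p_one_tailed,
         alternative = x$direction, method = "pooled two-proportion z-test")
}

#' @method glance prop_ztest
#' @export
glance.prop_ztest <- function(x, ...) {
  tibble(statistic = x$z, p.value = x$p_one_tailed,
         n1 = x$n1, n2 = x$n2)
}

#' Percentage with half-up rounding to two decimals
#'
#' @param x,n successes and total (\code{n >= 1}).
#' @return \code{100 * x / n} rounded half-up to 2 decimals.
#' @examples
#' proportion_percent(367, 1167)  # 31.45
#' @export
proportion_percent <- function(x, n) {
  if (any(n < 1)) abort("n must be >= 1")
  pct <- 100 * x / n
  floor(pct * 100 + 0.5 + sqrt(.Machine$double.eps)) / 100
}
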