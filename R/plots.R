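#' Plot an intersection summary as stacked orientation bars
#'
#' One bar per summary row (pseudogene set x lncRNA set x evidence tier),
#' partitioned into sense-only, antisense-only and complex (both-orientation)
#' loci.
#'
#' @param object output of [intersect_summary()].
#' @param ... ignored.
#' @return A ggplot object.
#' @method autoplot pg_summary
#' @export
autoplot.pg_summary <- function(object, ...) {
  plot_intersect_summary(object)
}

#' @rdname autoplot.pg_summary
#' @param summary output of [intersect_summary()].
#' @export
plot_intersect_summary <- function(summary) {
  long <- summary %>%
    mutate(row = paste(.data$file1, "/", .data$file2)) %>%
    tidyr::pivot_longer(c("sense_overlaps", "antisense_overlaps",
                          "complex_loci"),
                        names_to = "orientation", values_to = "n_loci") %>%
    mutate(orientation = factor(
      dplyr::recode(.data$orientation, sense_overlaps = "sense only",
                    antisense_overlaps = "antisense only",
                    complex_loci = "complex (both)"),
      levels = c("sense only", "antisense only", "complex (both)")))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$row, y = .data$n_loci,
                                     fill = .data$orientation)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "loci",
                  fill = "partner orientation",
                  title = "Pseudogene loci by partner orientation") +
    ggplot2::theme_minimal()
}

#' Plot the score distribution of an intersection result
#'
#' Span-span score against exon-exon score for every (focal, partner) pair,
#' colored by relative orientation. Identical gene structures sit at (1, 1);
#' marginal span brushes sit near the origin.
#'
#' @param object a \code{pg_hits} tibble from [intersect_models()].
#' @param ... ignored.
#' @return A ggplot object.
#' @method autoplot pg_hits
#' @export
autoplot.pg_hits <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$ss, y = .data$ee,
                               colour = .data$orientation)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::lims(x = c(0, 1), y = c(0, 1)) +
    ggplot2::labs(x = "span-span score (SS)", y = "exon-exon score (EE)",
                  colour = "orientation",
                  title = "Overlap quality per gene pair") +
    ggplot2::theme_minimal()
}

#' Plot non-redundant merge membership cells
#'
#' @param report the \code{report} element of [merge_catalogs()].
#' @return A ggplot object.
#' @export
plot_catalog_report <- function(report) {
  ggplot2::ggplot(as_tibble(report),
                  ggplot2::aes(x = stats::reorder(.data$cell, -.data$n_loci),
                               y = .data$n_loci)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "source membership", y = "non-redundant loci",
                  title = "Merged pseudogene catalog membership") +
    ggplot2::theme_minimal()
}
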