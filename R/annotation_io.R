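#' Read a GTF annotation set into a gene-model table
#'
#' Parses a 9-column tab-delimited GTF, keeps \code{exon}-typed rows, and
#' groups them by \code{gene_id} into gene models. Feature types other than
#' \code{exon} (including \code{transcript} rows) are ignored, so annotation
#' sets that ship only exon rows load identically to those with full gene
#' structure; the gene span is always derived from the exons. Gene ids whose
#' exons fall on more than one chromosome or strand are split into per-locus
#' models with suffixed ids (see [split_multi_locus()]).
#'
#' Coordinates are kept in the GTF convention: 1-based, both ends inclusive.
#'
#' @param path path to a GTF file.
#' @param source_tag annotation-set tag stored in the \code{source} column
#'   (defaults to the file name without extension).
#' @return A gene-model tibble (see [gene_models()]), one row per exon record.
#' @section Errors: a malformed line (wrong column count, \code{start > end},
#'   a strand other than \code{+}/\code{-}, non-numeric coordinates) or a
#'   missing \code{gene_id} attribute rejects the file with the offending
#'   line number.
#' @examples
#' f <- tempfile(fileext = ".gtf")
#' writeLines(paste("chr1", "demo", "exon", c(100, 400), c(200, 500), ".",
#'                  "+", ".", 'gene_id "G1"; transcript_id "G1.t1";',
#'                  sep = "\t"), f)
#' read_gtf(f, "demo")
#' @export
read_gtf <- function(path, source_tag = NULL) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  source_tag <- source_tag %||% sub("\\.[^.]*$", "", basename(path))
  lines <- readr::read_lines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  line_no <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) {
    return(gene_models(source = character(), chrom = character(),
                       start = integer(), end = integer(), strand = character(),
                       gene_id = character()))
  }
  fields <- stringr::str_split(lines, stringr::fixed("\t"))
  n_fields <- lengths(fields)
  if (any(n_fields != 9)) {
    bad <- which(n_fields != 9)[1]
    abort(sprintf("%s line %d: expected 9 tab-delimited columns, found %d",
                  path, line_no[bad], n_fields[bad]))
  }
  m <- matrix(unlist(fields), ncol = 9, byrow = TRUE)
  feature <- m[, 3]
  start <- suppressWarnings(as.integer(m[, 4]))
  end <- suppressWarnings(as.integer(m[, 5]))
  strand <- m[, 7]
  attrs <- m[, 9]

  exon <- feature == "exon"
  check <- function(bad, msg) {
    if (any(bad)) {
      i <- which(bad)[1]
      abort(sprintf("%s line %d: %s", path, line_no[i], msg[which(bad)[1]]))
    }
  }
  check(exon & (is.na(start) | is.na(end)), rep("non-numeric coordinate", length(exon)))
  check(exon & !is.na(start) & !is.na(end) & start > end,
        sprintf("start > end (%s > %s)", m[, 4], m[, 5]))
  check(exon & !strand %in% c("+", "-"),
        sprintf("unknown strand symbol '%s'", strand))

  gene_id <- gtf_attr(attrs, "gene_id")
  transcript_id <- gtf_attr(attrs, "transcript_id")
  check(exon & is.na(gene_id), rep("missing gene_id attribute", length(exon)))
  transcript_id[is.na(transcript_id)] <- gene_id[is.na(transcript_id)]

  if (!any(exon)) {
    return(gene_models(source = character(), chrom = character(),
                       start = integer(), end = integer(), strand = character(),
                       gene_id = character()))
  }
  out <- tibble(
    source = source_tag, chrom = m[exon, 1], start = start[exon],
    end = end[exon], strand = strand[exon], gene_id = gene_id[exon],
    transcript_id = transcript_id[exon], attributes = attrs[exon],
    file_order = seq_len(sum(exon))
  )
  split_multi_locus(validate_gene_models(out))
}

#' Extract a value from a GTF attribute string
#'
#' @param attributes character vector of GTF column-9 strings.
#' @param key attribute key, e.g. \code{"gene_id"}.
#' @return Character vector of values (\code{NA} where the key is absent).
#' @export
gtf_attr <- function(attributes, key) {
  out <- stringr::str_match(attributes,
                            paste0("(?:^|;)\\s*", key, '\\s+"([^"]*)"'))[, 2]
  out
}

#' Write a gene-model table back to GTF
#'
#' Emits one \code{exon} row per table row, preserving the stored attribute
#' strings, so \code{read_gtf(write_gtf(x, f))} round-trips field-by-field.
#'
#' @param models a gene-model tibble.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_gtf <- function(models, path) {
  validate_gene_models(models)
  lines <- sprintf("%s\t%s\texon\t%d\t%d\t.\t%s\t.\t%s",
                   models$chrom, models$source, models$start, models$end,
                   models$strand, models$attributes)
  readr::write_lines(lines, path)
  invisible(path)
}

#' Remove entries with duplicated identifiers
#'
#' Two records are redundant at the id level when they share gene id,
#' transcript id and coordinates: re-listed entries of the same gene (accession
#' synonymy within one set, or the same file loaded twice) collapse to their
#' first occurrence in file order. Entries sharing a gene id but carrying
#' disjoint transcript-id sets are distinct and all retained. The number of
#' removed records is reported with a message. Idempotent.
#'
#' @param models a gene-model tibble.
#' @return The tibble restricted to the retained records.
#' @export
deduplicate_ids <- function(models) {
  validate_gene_models(models)
  if (nrow(models) == 0) return(models)
  kept <- models %>%
    arrange(.data$file_order) %>%
    distinct(.data$chrom, .data$start, .data$end, .data$strand,
             .data$gene_id, .data$transcript_id, .keep_all = TRUE)
  n_removed <- nrow(models) - nrow(kept)
  if (n_removed > 0) {
    inform(sprintf("deduplicate_ids: removed %d redundant exon record%s",
                   n_removed, if (n_removed == 1) "" else "s"))
  }
  kept
}

#' Normalize EST orientation from read-end metadata
#'
#' 3' ESTs are sequenced from the transcript's 3' end and are conventionally
#' reported on the strand opposite to the transcript's biological direction.
#' This flips the strand of every record tagged as a 3' read so downstream
#' sense/antisense calls reflect the true direction of transcription; 5' and
#' untagged records pass through unchanged. Coordinates are never touched and
#' applying the operation twice restores the input (involution).
#'
#' @param models a gene-model tibble of ESTs.
#' @param read_end either a character vector (one of \code{"5prime"},
#'   \code{"3prime"}, \code{"unknown"} per row), or \code{NULL} to read the
#'   value from the GTF attribute named by \code{attr_key}.
#' @param attr_key attribute key holding the read end (default
#'   \code{"read_end"}).
#' @return The tibble with strands normalized.
#' @export
normalize_est_orientation <- function(models, read_end = NULL,
                                      attr_key = "read_end") {
  validate_gene_models(models)
  if (is.null(read_end)) {
    read_end <- gtf_attr(models$attributes, attr_key)
    read_end[is.na(read_end)] <- "unknown"
  }
  read_end <- rep_len(as.character(read_end), nrow(models))
  bad <- !read_end %in% c("5prime", "3prime", "unknown")
  if (any(bad)) {
    abort(sprintf("invalid read_end value '%s'", read_end[which(bad)[1]]))
  }
  flip <- read_end == "3prime"
  models %>%
    mutate(strand = if_else(flip, if_else(.data$strand == "+", "-", "+"),
                            .data$strand))
}

#' Read point or interval features from BED or TSV
#'
#' BED input is 0-based half-open and is converted to the package's 1-based
#' inclusive convention (\code{start + 1}); a 1-bp BED feature
#' \code{chr1 99 100} therefore lands at position 100. TSV input (e.g. a GWAS
#' SNP catalog) is read with a declared column mapping and yields 1-bp
#' features.
#'
#' @param path input file.
#' @param format \code{"bed"} or \code{"tsv"}.
#' @param columns for \code{format = "tsv"}, a named list mapping the roles
#'   \code{id}, \code{chrom}, \code{pos} and (optionally) \code{payload} to
#'   column names or 1-based column indices in the file.
#' @param header for \code{format = "tsv"}, whether the file has a header row.
#' @return A tibble with columns \code{id}, \code{chrom}, \code{start},
#'   \code{end}, \code{position} (\code{= start}) and \code{payload}
#'   (trait/annotation text, \code{NA} when absent).
#' @export
read_point_features <- function(path, format = c("bed", "tsv"),
                                columns = list(id = 1, chrom = 2, pos = 3,
                                               payload = 4),
                                header = format == "tsv") {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  if (format == "bed") {
    df <- readr::read_tsv(path, col_names = FALSE, col_types = readr::cols(),
                          comment = "#", progress = FALSE)
    if (nrow(df) == 0) {
      return(tibble(id = character(), chrom = character(), start = integer(),
                    end = integer(), position = integer(),
                    payload = character()))
    }
    if (ncol(df) < 3) abort("BED input needs at least 3 columns")
    out <- tibble(
      id = if (ncol(df) >= 4) as.character(df[[4]]) else
        sprintf("feat%d", seq_len(nrow(df))),
      chrom = as.character(df[[1]]),
      start = as.integer(df[[2]]) + 1L,
      end = as.integer(df[[3]]),
      payload = NA_character_
    )
  } else {
    need <- c("id", "chrom", "pos")
    if (!all(need %in% names(columns))) {
      abort(paste0("TSV column mapping must name: ",
                   paste(need, collapse = ", ")))
    }
    df <- readr::read_tsv(path, col_names = header || FALSE,
                          col_types = readr::cols(), comment = "#",
                          progress = FALSE, show_col_types = FALSE)
    if (!header) names(df) <- paste0("X", seq_along(df))
    resolve <- function(spec) {
      if (is.numeric(spec)) {
        if (spec > ncol(df)) abort(sprintf("column index %d out of range", spec))
        return(df[[spec]])
      }
      if (!spec %in% names(df)) abort(paste0("no such column: ", spec))
      df[[spec]]
    }
    if (nrow(df) == 0) {
      return(tibble(id = character(), chrom = character(), start = integer(),
                    end = integer(), position = integer(),
                    payload = character()))
    }
    pos <- as.integer(resolve(columns$pos))
    out <- tibble(
      id = as.character(resolve(columns$id)),
      chrom = as.character(resolve(columns$chrom)),
      start = pos, end = pos,
      payload = if (!is.null(columns$payload))
        as.character(resolve(columns$payload)) else NA_character_
    )
  }
  if (any(is.na(out$start) | is.na(out$end))) {
    abort("non-numeric position in point-feature input")
  }
  out %>% mutate(position = .data$start, .after = "end")
}
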