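# Independent brute-force oracles: per-base enumeration and union-find,
# deliberately written without reusing any package internals.

bf_overlap_length <- function(c1, s1, e1, c2, s2, e2) {
  if (c1 != c2) return(0L)
  length(intersect(seq.int(s1, e1), seq.int(s2, e2)))
}

# per-base span-span score: reciprocal covered fractions multiplied
bf_span_score <- function(g1, g2) {
  sp1 <- c(min(g1$start), max(g1$end))
  sp2 <- c(min(g2$start), max(g2$end))
  if (unique(g1$chrom) != unique(g2$chrom)) return(0)
  b1 <- seq.int(sp1[1], sp1[2])
  b2 <- seq.int(sp2[1], sp2[2])
  shared <- length(intersect(b1, b2))
  (shared / length(b1)) * (shared / length(b2))
}

# per-base exon-exon score: every overlapping exon pair contributes
# E = (covered fraction of exon 1) * (covered fraction of exon 2);
# TE = #exons(g1) + #exons(g2) overlapping no g1 exon; EE = sum(E) / TE
bf_exon_score <- function(g1, g2) {
  ex1 <- unique(g1[, c("chrom", "start", "end")])
  ex2 <- unique(g2[, c("chrom", "start", "end")])
  sum_e <- 0
  matched2 <- logical(nrow(ex2))
  for (i in seq_len(nrow(ex1))) {
    b1 <- seq.int(ex1$start[i], ex1$end[i])
    for (j in seq_len(nrow(ex2))) {
      if (ex1$chrom[i] != ex2$chrom[j]) next
      b2 <- seq.int(ex2$start[j], ex2$end[j])
      shared <- length(intersect(b1, b2))
      if (shared > 0) {
        matched2[j] <- TRUE
        sum_e <- sum_e + (shared / length(b1)) * (shared / length(b2))
      }
    }
  }
  te <- nrow(ex1) + sum(!matched2)
  list(te = te, ee = sum_e / te)
}

# single-linkage clustering oracle: union-find over the pairwise
# span-overlap graph
uf_clusters <- function(spans) {
  n <- nrow(spans)
  parent <- seq_len(n)
  find2 <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i >= j) next
      if (spans$chrom[i] == spans$chrom[j] &&
          spans$start[i] <= spans$end[j] && spans$start[j] <= spans$end[i]) {
        ri <- find2(i); rj <- find2(j)
        if (ri != rj) parent[rj] <- ri
      }
    }
  }
  vapply(seq_len(n), find2, integer(1))
}
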