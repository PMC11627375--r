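# Independent brute-force oracles. Each recomputes a quantity by exhaustive
# per-base / pairwise enumeration, deliberately ignoring the package's
# implementation path.

# Total covered bp via a per-base boolean array (small coordinates only).
oracle_covered_bp <- function(intervals, max_coord) {
  total <- 0
  for (ch in unique(intervals$chrom)) {
    covered <- rep(FALSE, max_coord)
    rows <- intervals[intervals$chrom == ch, ]
    for (i in seq_len(nrow(rows))) {
      covered[seq(rows$start[i] + 1, rows$end[i])] <- TRUE
    }
    total <- total + sum(covered)
  }
  total
}

# Per-base depth oracle for coverage_segments: for each chromosome build a
# label x base matrix, find runs of bases covered by >= min_labels labels.
oracle_coverage_segments <- function(interval_sets, min_labels, max_coord) {
  labels <- names(interval_sets)
  chroms <- unique(unlist(lapply(interval_sets, function(x) x$chrom)))
  out <- list()
  for (ch in sort(chroms)) {
    cov <- matrix(FALSE, nrow = length(labels), ncol = max_coord)
    for (li in seq_along(labels)) {
      rows <- interval_sets[[li]]
      rows <- rows[rows$chrom == ch, ]
      for (i in seq_len(nrow(rows))) {
        cov[li, seq(rows$start[i] + 1, rows$end[i])] <- TRUE
      }
    }
    qual <- colSums(cov) >= min_labels
    r <- rle(qual)
    ends <- cumsum(r$lengths)
    starts <- c(0, ends[-length(ends)])
    keep <- which(r$values)
    for (k in keep) {
      seg_start <- starts[k]
      seg_end <- ends[k]
      overlapping <- labels[vapply(seq_along(labels), function(li) {
        any(cov[li, seq(seg_start + 1, seg_end)])
      }, logical(1))]
      out[[length(out) + 1]] <- tibble::tibble(
        chrom = ch, start = seg_start, end = seg_end,
        labels = list(sort(overlapping)))
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(chrom = character(), start = numeric(),
                          end = numeric(), labels = list()))
  }
  dplyr::bind_rows(out)
}

# O(n^2) pairwise-linkage clustering oracle: connect any two variants on one
# chromosome within max_gap, take connected components.
oracle_cluster <- function(variants, max_gap) {
  n <- nrow(variants)
  if (n == 0) return(list(n_clusters = 0L, n_multi = 0L))
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      adj[i, j] <- variants$chrom[i] == variants$chrom[j] &&
        abs(variants$pos[i] - variants$pos[j]) <= max_gap
    }
  }
  # transitive closure
  repeat {
    nxt <- adj | (adj %*% adj > 0)
    if (identical(nxt, adj)) break
    adj <- nxt
  }
  comp <- rep(NA_integer_, n)
  k <- 0L
  for (i in seq_len(n)) {
    if (is.na(comp[i])) {
      k <- k + 1L
      comp[which(adj[i, ])] <- k
    }
  }
  n_multi <- sum(vapply(seq_len(k), function(cl) {
    length(unique(variants$cancer[comp == cl])) >= 2
  }, logical(1)))
  list(n_clusters = k, n_multi = n_multi)
}

# Nested-loop distinct-signal count oracle.
oracle_signal_counts <- function(regions, variants) {
  out <- list()
  for (r in seq_len(nrow(regions))) {
    for (cc in unique(variants$cancer)) {
      sigs <- character()
      for (i in seq_len(nrow(variants))) {
        v <- variants[i, ]
        if (v$is_index && v$cancer == cc && v$chrom == regions$chrom[r] &&
            v$pos >= regions$start[r] && v$pos < regions$end[r]) {
          sigs <- union(sigs, v$signal_id)
        }
      }
      if (length(sigs)) {
        out[[length(out) + 1]] <- tibble::tibble(
          region_id = regions$region_id[r], cancer = cc,
          n_signals = length(sigs))
      }
    }
  }
  dplyr::bind_rows(out)
}

# Per-variant, per-gene location oracle by explicit membership checks.
oracle_classify <- function(variants, gm, flank = 2000) {
  out <- list()
  for (i in seq_len(nrow(variants))) {
    p <- variants$pos[i]
    for (g in seq_len(nrow(gm$genes))) {
      gene <- gm$genes[g, ]
      if (gene$chrom != variants$chrom[i]) next
      ex <- gm$exons[gm$exons$gene_id == gene$gene_id, ]
      in_exon <- any(p >= ex$start & p < ex$end)
      in_prom <- p >= gene$tss - flank && p <= gene$tss + flank
      in_span <- p >= gene$start && p < gene$end
      cls <- if (in_exon) "exonic" else if (in_prom) "promoter" else if (in_span) "intronic" else NA
      if (!is.na(cls)) {
        out[[length(out) + 1]] <- tibble::tibble(
          variant_id = variants$variant_id[i], gene_id = gene$gene_id,
          location_class = cls)
      }
    }
  }
  dplyr::bind_rows(out) |> dplyr::arrange(variant_id, gene_id)
}

# Exhaustive (interaction x TAD) within-TAD count using fragment midpoints.
oracle_within_tad <- function(interactions, tads) {
  mid <- function(s, e) floor((s + e) / 2)
  count <- 0L
  for (i in seq_len(nrow(interactions))) {
    m1 <- mid(interactions$bait_start[i], interactions$bait_end[i])
    m2 <- mid(interactions$oe_start[i], interactions$oe_end[i])
    hit <- FALSE
    for (t in seq_len(nrow(tads))) {
      if (interactions$bait_chrom[i] == tads$chrom[t] &&
          interactions$oe_chrom[i] == tads$chrom[t] &&
          m1 >= tads$start[t] && m1 < tads$end[t] &&
          m2 >= tads$start[t] && m2 < tads$end[t]) {
        hit <- TRUE
        break
      }
    }
    if (hit) count <- count + 1L
  }
  count
}

# One-sided (greater) Fisher p by explicit hypergeometric summation.
oracle_fisher_p <- function(a, b, c, d) {
  n_cand <- a + b
  big_k <- a + c
  big_n <- a + b + c + d
  x_max <- min(n_cand, big_k)
  sum(vapply(a:x_max, function(x) {
    choose(big_k, x) * choose(big_n - big_k, n_cand - x) / choose(big_n, n_cand)
  }, numeric(1)))
}

# Rank-then-Pearson Spearman oracle.
oracle_spearman <- function(x, y) {
  stats::cor(rank(x), rank(y), method = "pearson")
}

# Random small interval set on toy chromosomes.
random_intervals <- function(n, chroms = c("chrA", "chrB"), max_coord = 1000) {
  start <- sample.int(max_coord - 1, n, replace = TRUE) - 1
  len <- sample.int(50, n, replace = TRUE)
  tibble::tibble(chrom = sample(chroms, n, replace = TRUE),
                 start = start, end = pmin(start + len, max_coord))
}

# Tiny deterministic assembly for unit fixtures.
toy_assembly <- function(len = 1e6, chroms = c("chr1", "chr2")) {
  genome_assembly(chroms, rep(len, length(chroms)))
}

# Hand-built gene models: one +strand and one -strand gene on chr1.
toy_gene_models <- function() {
  genes <- tibble::tibble(
    gene_id = c("gplus", "gminus", "lnc1"),
    name = c("GPLUS", "GMINUS", "LNC1"),
    biotype = c("protein_coding", "protein_coding", "lncRNA"),
    chrom = "chr1",
    strand = c("+", "-", "+"))
  exons <- tibble::tibble(
    gene_id = c("gplus", "gplus", "gminus", "gminus", "lnc1"),
    chrom = "chr1",
    start = c(100000, 110000, 200000, 220000, 400000),
    end = c(100500, 111000, 201000, 221000, 401000))
  gene_models(genes, exons)
}

toy_variants <- function(ids, chrom, pos, cancer,
                         signal_id = NULL, is_index = TRUE, r2 = 1) {
  if (is.null(signal_id)) signal_id <- ids
  tibble::tibble(variant_id = ids, chrom = chrom, pos = pos, cancer = cancer,
                 signal_id = signal_id, is_index = is_index, r2 = r2)
}
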