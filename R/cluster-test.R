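#' Single-linkage clustering of variants along the genome
#'
#' Groups variants per chromosome by single linkage: consecutive
#' position-sorted variants join one cluster when the gap between them is at
#' most `max_gap` (100 kb by default, the window used to call co-localised
#' multi-trait clusters). A cluster is "multi-trait" when it contains variants
#' from two or more distinct trait labels.
#'
#' @param variants Variant tibble (see [read_variants()]).
#' @param max_gap Maximum gap in bp between consecutive variants in one
#'   cluster (>= 0); in tiling mode, the fixed window width.
#' @param method `"linkage"` (default; `bedtools cluster -d` semantics) or
#'   `"tiling"`, a sensitivity-analysis mode that bins variants into fixed
#'   genomic windows of width `max_gap` instead.
#' @return A list of class `cluster_result` with `assignments` (tibble
#'   `variant_id`, `cancer`, `chrom`, `pos`, `cluster`), `n_clusters` and
#'   `n_multi_trait_clusters`.
#' @export
cluster_variants <- function(variants, max_gap = 100000,
                             method = c("linkage", "tiling")) {
  method <- match.arg(method)
  if (!is.numeric(max_gap) || length(max_gap) != 1L || is.na(max_gap) ||
      max_gap < 0 || (method == "tiling" && max_gap == 0)) {
    abort("`max_gap` must be a single non-negative number.")
  }
  o <- order(variants$chrom, variants$pos)
  chrom <- variants$chrom[o]
  pos <- variants$pos[o]
  n <- length(pos)
  if (n == 0L) {
    return(structure(list(assignments = mutate(variants, cluster = integer()),
                          n_clusters = 0L, n_multi_trait_clusters = 0L),
                     class = "cluster_result"))
  }
  if (method == "tiling") {
    tile <- floor(pos / max_gap)
    new_cluster <- c(TRUE, chrom[-1] != chrom[-n] | diff(tile) != 0)
  } else {
    new_cluster <- c(TRUE, chrom[-1] != chrom[-n] | diff(pos) > max_gap)
  }
  cl <- cumsum(new_cluster)
  cancer_code <- as.integer(factor(variants$cancer[o]))
  counts <- multi_trait_count(cl, cancer_code)
  assignments <- tibble(
    variant_id = variants$variant_id[o],
    cancer = variants$cancer[o],
    chrom = chrom, pos = pos, cluster = cl
  )
  structure(
    list(assignments = assignments,
         n_clusters = counts$n_clusters,
         n_multi_trait_clusters = counts$n_multi),
    class = "cluster_result"
  )
}

# Count clusters and clusters holding >= 2 distinct trait codes.
# cl: sorted integer cluster ids; code: trait code per variant (1..K).
multi_trait_count <- function(cl, code) {
  k <- max(code)
  key <- sort.int((cl - 1L) * k + code, method = "radix")
  distinct <- key[c(TRUE, diff(key) != 0L)]
  per_cluster <- tabulate((distinct - 1L) %/% k + 1L, nbins = cl[length(cl)])
  list(n_clusters = cl[length(cl)], n_multi = sum(per_cluster >= 2L))
}

#' Shuffle variant positions preserving chromosomal distribution
#'
#' Each variant receives an independent uniform position in `[0, length)` on
#' its own chromosome; chromosome, trait label and signal identity are
#' untouched, so per-(chromosome, trait) counts are conserved exactly. This is
#' the null model of the clustering permutation test.
#'
#' @param variants Variant tibble.
#' @param assembly A [genome_assembly()].
#' @param rng_seed Optional integer seed; when given, the RNG state is set
#'   locally and restored afterwards.
#' @param exclude Optional interval tibble (`chrom`, `start`, `end`) of
#'   regions (e.g. assembly gaps, centromeres) variants may not land in;
#'   positions are redrawn until they fall outside.
#' @return A variant tibble with new `pos` values.
#' @export
shuffle_variants <- function(variants, assembly, rng_seed = NULL,
                             exclude = NULL) {
  check_chroms(variants$chrom, assembly, "variant")
  len <- chrom_length(assembly, variants$chrom)
  with_seed(rng_seed, {
    pos <- runif_pos(nrow(variants), len)
    if (!is.null(exclude) && nrow(exclude)) {
      for (iter in 1:1000) {
        bad <- !is.na(GenomicRanges::findOverlaps(
          iv_to_gr(tibble(chrom = variants$chrom, start = pos, end = pos + 1)),
          iv_to_gr(exclude), select = "first"))
        if (!any(bad)) break
        pos[bad] <- runif_pos(sum(bad), len[bad])
      }
      if (any(bad)) abort("Could not place variants outside `exclude`.")
    }
    variants$pos <- pos
    variants
  })
}

#' Permutation test for multi-trait spatial clustering
#'
#' Tests whether variants from multiple traits co-localise within `max_gap`
#' windows more often than expected by chance. The observed statistic is the
#' number of multi-trait clusters ([cluster_variants()]); the null
#' distribution is obtained by uniformly re-placing every variant on its own
#' chromosome (all traits shuffled jointly and independently each iteration)
#' and recounting. The p-value is one-sided for enrichment:
#' `#\{null >= observed\} / n_perms`.
#'
#' @param variants Variant tibble.
#' @param assembly A [genome_assembly()].
#' @param max_gap Clustering gap in bp (default 100 kb).
#' @param n_perms Number of permutations (>= 1; default 10000 — raise to 1e6
#'   for publication-grade p-value resolution).
#' @param rng_seed Integer seed for reproducibility.
#' @param smoothed Use the add-one smoothed p estimator `(k+1)/(n+1)`.
#' @param method Clustering mode, passed to [cluster_variants()].
#' @param exclude Optional exclusion intervals for the shuffle (see
#'   [shuffle_variants()]); the default shuffles over whole chromosomes.
#' @return A [perm_test_result()] with the observed multi-trait cluster count.
#' @export
clustering_permutation_test <- function(variants, assembly,
                                        max_gap = 100000,
                                        n_perms = 10000,
                                        rng_seed = NULL,
                                        smoothed = FALSE,
                                        method = c("linkage", "tiling"),
                                        exclude = NULL) {
  method <- match.arg(method)
  if (!is_count(n_perms) || n_perms < 1) abort("`n_perms` must be >= 1.")
  check_chroms(variants$chrom, assembly, "variant")
  # Canonicalise the row order so the null stream (and hence the p-value)
  # does not depend on how the input file happened to be sorted.
  variants <- variants[order(chrom_rank(variants$chrom, assembly),
                             variants$pos, variants$cancer,
                             variants$variant_id), ]
  observed <- cluster_variants(variants, max_gap,
                               method = method)$n_multi_trait_clusters

  # Precompute sort-stable scaffolding: chromosomes as integer ranks so each
  # permutation only draws positions, orders, and counts.
  chrom_idx <- chrom_rank(variants$chrom, assembly)
  len <- assembly$length[chrom_idx]
  cancer_code <- as.integer(factor(variants$cancer))
  n <- nrow(variants)
  big <- max(assembly$length) + 1

  null_values <- with_seed(rng_seed, {
    vapply(seq_len(n_perms), function(i) {
      if (is.null(exclude)) {
        pos <- runif_pos(n, len)
      } else {
        pos <- shuffle_variants(variants, assembly, exclude = exclude)$pos
      }
      o <- order(chrom_idx * big + pos, method = "radix")
      ci <- chrom_idx[o]
      p <- pos[o]
      if (method == "tiling") {
        tile <- floor(p / max_gap)
        new_cluster <- c(TRUE, ci[-1] != ci[-n] | diff(tile) != 0)
      } else {
        new_cluster <- c(TRUE, ci[-1] != ci[-n] | diff(p) > max_gap)
      }
      multi_trait_count(cumsum(new_cluster), cancer_code[o])$n_multi
    }, numeric(1))
  })
  perm_test_result(observed, null_values,
                   seed = rng_seed %||% NA_integer_, smoothed = smoothed)
}
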