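#' Read a restriction fragment map (BED4)
#'
#' Fragments must tile each chromosome without overlap; the fragment id is
#' taken from the BED name column (or assigned by row when absent).
#'
#' @param path Path to a BED4 file.
#' @param assembly Optional [genome_assembly()] for validation.
#' @return Tibble `fragment_id`, `chrom`, `start`, `end`.
#' @export
read_fragments <- function(path, assembly = NULL) {
  bed <- read_bed(path, assembly)
  tibble(
    fragment_id = if ("name" %in% names(bed)) bed$name else as.character(seq_len(nrow(bed))),
    chrom = bed$chrom, start = bed$start, end = bed$end
  )
}

#' Write a fragment map as BED4
#' @param fragments Fragment tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fragments <- function(fragments, path) {
  write_bed(tibble(chrom = fragments$chrom, start = fragments$start,
                   end = fragments$end, name = fragments$fragment_id), path)
}

#' Read TAD intervals (BED3)
#'
#' Within one annotation set, TADs on a chromosome must not overlap; when they
#' do, the later (by start) offending TADs are dropped with a message.
#'
#' @param path Path to a BED3 file.
#' @param assembly Optional [genome_assembly()].
#' @return Tibble `chrom`, `start`, `end`, sorted.
#' @export
read_tads <- function(path, assembly = NULL) {
  tads <- read_bed(path, assembly)[, c("chrom", "start", "end")]
  enforce_disjoint_tads(tads)
}

enforce_disjoint_tads <- function(tads) {
  tads <- arrange(tads, .data$chrom, .data$start)
  keep <- rep(TRUE, nrow(tads))
  last_end <- -Inf
  last_chrom <- ""
  for (i in seq_len(nrow(tads))) {
    if (tads$chrom[i] != last_chrom) {
      last_chrom <- tads$chrom[i]
      last_end <- -Inf
    }
    if (tads$start[i] < last_end) {
      keep[i] <- FALSE
    } else {
      last_end <- tads$end[i]
    }
  }
  if (!all(keep)) {
    inform(paste0("Dropped ", sum(!keep), " overlapping TAD(s)."))
  }
  tads[keep, ]
}

#' Read chromatin interaction calls
#'
#' Accepts the CHiCAGO ibed dialect (header
#' `bait_chr bait_start bait_end bait_name otherEnd_chr otherEnd_start
#' otherEnd_end otherEnd_name N_reads score`) or headerless BEDPE with a
#' score column (`chrom1 start1 end1 chrom2 start2 end2 name score`), one
#' file per cell line. Coordinates are 0-based half-open throughout.
#'
#' @param path Path to the interaction file.
#' @param cell_line Cell line label attached to every interaction.
#' @param format `"ibed"` or `"bedpe"`.
#' @return Tibble `bait_chrom`, `bait_start`, `bait_end`, `oe_chrom`,
#'   `oe_start`, `oe_end`, `cell_line`, `n_reads`, `score`.
#' @export
read_interactions <- function(path, cell_line, format = c("ibed", "bedpe")) {
  format <- match.arg(format)
  if (format == "ibed") {
    df <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "")
    tibble(
      bait_chrom = as.character(df$bait_chr),
      bait_start = as.numeric(df$bait_start),
      bait_end = as.numeric(df$bait_end),
      oe_chrom = as.character(df$otherEnd_chr),
      oe_start = as.numeric(df$otherEnd_start),
      oe_end = as.numeric(df$otherEnd_end),
      cell_line = cell_line,
      n_reads = as.numeric(df$N_reads),
      score = as.numeric(df$score)
    )
  } else {
    df <- utils::read.table(path, sep = "\t", header = FALSE, comment.char = "")
    tibble(
      bait_chrom = as.character(df[[1]]), bait_start = as.numeric(df[[2]]),
      bait_end = as.numeric(df[[3]]),
      oe_chrom = as.character(df[[4]]), oe_start = as.numeric(df[[5]]),
      oe_end = as.numeric(df[[6]]),
      cell_line = cell_line,
      n_reads = NA_real_,
      score = as.numeric(df[[8]])
    )
  }
}

#' Write interactions in the ibed dialect
#' @param interactions Interaction tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_interactions <- function(interactions, path) {
  df <- data.frame(
    bait_chr = interactions$bait_chrom,
    bait_start = interactions$bait_start,
    bait_end = interactions$bait_end,
    bait_name = ".",
    otherEnd_chr = interactions$oe_chrom,
    otherEnd_start = interactions$oe_start,
    otherEnd_end = interactions$oe_end,
    otherEnd_name = ".",
    N_reads = interactions$n_reads,
    score = interactions$score
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Keep high-confidence interactions
#'
#' Retains interactions whose CHiCAGO score is at least `min_score`
#' (default 5, the high-confidence threshold; the boundary value 5.0 is
#' kept). Input order is preserved; the operation is idempotent.
#'
#' @param interactions Interaction tibble.
#' @param min_score Minimum score, inclusive (default 5).
#' @return Filtered interaction tibble.
#' @export
filter_interactions <- function(interactions, min_score = 5) {
  interactions[interactions$score >= min_score, , drop = FALSE]
}

#' Spearman concordance between replicate libraries
#'
#' Rank correlation of raw read counts over the union of interaction fragment
#' pairs of two replicates; a pair absent from one replicate contributes a
#' count of 0 there. Undefined (with flag) when fewer than 3 pairs are shared.
#'
#' @param rep1,rep2 Interaction tibbles carrying `n_reads` (see
#'   [read_interactions()]).
#' @return List `rho`, `n_pairs` (union size), `defined`.
#' @export
replicate_concordance <- function(rep1, rep2) {
  key <- function(x) {
    paste(x$bait_chrom, x$bait_start, x$bait_end,
          x$oe_chrom, x$oe_start, x$oe_end, sep = ":")
  }
  k1 <- key(rep1); k2 <- key(rep2)
  all_keys <- union(k1, k2)
  n_shared <- length(intersect(k1, k2))
  if (n_shared < 3) {
    return(list(rho = NA_real_, n_pairs = length(all_keys), defined = FALSE))
  }
  c1 <- rep1$n_reads[match(all_keys, k1)]
  c2 <- rep2$n_reads[match(all_keys, k2)]
  c1[is.na(c1)] <- 0
  c2[is.na(c2)] <- 0
  rho <- stats::cor(c1, c2, method = "spearman")
  list(rho = rho, n_pairs = length(all_keys), defined = is.finite(rho))
}

fragment_midpoint <- function(start, end) floor((start + end) / 2)

# TAD index (or NA) for point positions; TADs are disjoint per chromosome.
tad_of_point <- function(chrom, pos, tads) {
  if (is.null(tads) || nrow(tads) == 0L) return(rep(NA_integer_, length(pos)))
  hits <- GenomicRanges::findOverlaps(
    iv_to_gr(tibble(chrom = chrom, start = pos, end = pos + 1)),
    iv_to_gr(tads), select = "first")
  as.integer(hits)
}

#' Assign distal regulatory variants to target genes through interactions
#'
#' A (variant, gene) link is emitted when (i) the variant is intergenic
#' (optionally also intronic-distal via `include_intronic`), (ii) it is
#' called regulatory ([is_regulatory()]), (iii) the restriction fragment
#' containing the variant is the other end of a (pre-filtered) interaction
#' whose bait fragment overlaps the gene's promoter. Cell lines are
#' aggregated over all supporting interactions. `within_tad` is `TRUE` when
#' any supporting interaction has both fragment midpoints inside the same
#' TAD. Variants not contained in any fragment are reported and skipped.
#'
#' @param variants Variant tibble.
#' @param fragments Fragment tibble ([read_fragments()]).
#' @param interactions Interaction tibble, already score-filtered
#'   ([filter_interactions()]).
#' @param gm A [gene_models()] object.
#' @param annotation An `annotation_scores` list ([read_scores()]).
#' @param tads TAD tibble, or `NULL` (then `within_tad` is `FALSE`
#'   everywhere, with a message).
#' @param location Optional precomputed [classify_location()] table.
#' @param include_intronic Also link intronic regulatory variants (default
#'   `FALSE`: distal means outside any gene).
#' @param promoter_flank Promoter half-width in bp (default 2000).
#' @return Tibble `variant_id`, `gene_id`, `cell_lines` (list-column of
#'   character vectors), `within_tad`.
#' @export
assign_distal <- function(variants, fragments, interactions, gm, annotation,
                          tads = NULL, location = NULL,
                          include_intronic = FALSE, promoter_flank = 2000) {
  empty <- tibble(variant_id = character(), gene_id = character(),
                  cell_lines = list(), within_tad = logical())
  if (nrow(interactions) == 0L || nrow(variants) == 0L) return(empty)
  if (is.null(tads)) {
    inform("No TADs supplied; `within_tad` will be FALSE for every link.")
  }
  location <- location %||% classify_location(variants, gm, promoter_flank)
  loc_summary <- summarize_location(variants, location)
  eligible_classes <- c("intergenic", if (include_intronic) "intronic")
  reg <- annotation$scores$variant_id[is_regulatory(annotation$scores$regulome_probability)]
  cand <- variants |>
    inner_join(loc_summary, by = "variant_id") |>
    filter(.data$location_summary %in% eligible_classes,
           .data$variant_id %in% reg) |>
    distinct(.data$variant_id, .data$chrom, .data$pos)
  if (nrow(cand) == 0L) return(empty)

  # Fragment containing each candidate variant.
  vfrag <- GenomicRanges::findOverlaps(
    iv_to_gr(tibble(chrom = cand$chrom, start = cand$pos, end = cand$pos + 1)),
    iv_to_gr(fragments), select = "first")
  if (anyNA(vfrag)) {
    inform(paste0(sum(is.na(vfrag)),
                  " regulatory variant(s) fall outside the fragment map;",
                  " skipped."))
  }
  cand <- cand[!is.na(vfrag), , drop = FALSE]
  cand$fragment_id <- fragments$fragment_id[vfrag[!is.na(vfrag)]]
  if (nrow(cand) == 0L) return(empty)

  # Other-end fragment of each interaction (by other-end midpoint).
  oe_mid <- fragment_midpoint(interactions$oe_start, interactions$oe_end)
  oe_frag <- GenomicRanges::findOverlaps(
    iv_to_gr(tibble(chrom = interactions$oe_chrom, start = oe_mid,
                    end = oe_mid + 1)),
    iv_to_gr(fragments), select = "first")
  ints <- interactions
  ints$oe_fragment_id <- fragments$fragment_id[oe_frag]
  ints$bait_mid <- fragment_midpoint(ints$bait_start, ints$bait_end)
  ints$oe_mid <- oe_mid

  # Genes whose promoter overlaps the bait interval.
  prom <- promoter_intervals(gm, flank = promoter_flank)
  bait_gene <- GenomicRanges::findOverlaps(
    iv_to_gr(tibble(chrom = ints$bait_chrom, start = ints$bait_start,
                    end = ints$bait_end)),
    iv_to_gr(prom))
  if (length(bait_gene) == 0L) return(empty)
  links <- tibble(
    int = S4Vectors::queryHits(bait_gene),
    gene_id = prom$gene_id[S4Vectors::subjectHits(bait_gene)]
  )
  links <- bind_cols(links,
                     ints[links$int, c("oe_fragment_id", "cell_line",
                                       "bait_chrom", "bait_mid",
                                       "oe_chrom", "oe_mid")])
  links <- inner_join(links, cand[, c("variant_id", "fragment_id")],
                      by = c(oe_fragment_id = "fragment_id"),
                      relationship = "many-to-many")
  if (nrow(links) == 0L) return(empty)

  bait_tad <- tad_of_point(links$bait_chrom, links$bait_mid, tads)
  oe_tad <- tad_of_point(links$oe_chrom, links$oe_mid, tads)
  links$within_tad <- !is.na(bait_tad) & !is.na(oe_tad) & bait_tad == oe_tad

  links |>
    group_by(.data$variant_id, .data$gene_id) |>
    summarise(cell_lines = list(sort(unique(.data$cell_line))),
              within_tad = any(.data$within_tad), .groups = "drop") |>
    arrange(.data$variant_id, .data$gene_id)
}

#' Enrichment of interactions within TADs (circularised shuffle test)
#'
#' The observed statistic is the number of interactions whose bait and
#' other-end fragment midpoints fall inside one and the same TAD. The null is
#' generated by shifting each TAD independently by a uniform offset modulo
#' the length of its containing multi-cancer region: the region is treated as
#' a circle, so a TAD pushed past the region end wraps around to the region
#' start (occupying a suffix and a prefix but still counting as one TAD),
#' which conserves each TAD's length exactly. TADs not fully contained in any
#' region are ignored; interactions are attributed to the region of their
#' bait midpoint. One-sided p for enrichment.
#'
#' @param interactions Interaction tibble (already score-filtered).
#' @param tads TAD tibble.
#' @param regions Region tibble ([build_mhdcr_regions()]).
#' @param n_perms Number of permutations (default 10000).
#' @param rng_seed Integer seed.
#' @return A [perm_test_result()].
#' @export
tad_enrichment <- function(interactions, tads, regions, n_perms = 10000,
                           rng_seed = NULL) {
  if (!is_count(n_perms) || n_perms < 1) abort("`n_perms` must be >= 1.")
  # Assign TADs to the region fully containing them.
  tad_region <- GenomicRanges::findOverlaps(
    iv_to_gr(tads), iv_to_gr(regions), type = "within", select = "first")
  bait_mid <- fragment_midpoint(interactions$bait_start, interactions$bait_end)
  oe_mid <- fragment_midpoint(interactions$oe_start, interactions$oe_end)

  per_region <- list()
  for (r in seq_len(nrow(regions))) {
    t_idx <- which(tad_region == r)
    if (length(t_idx) == 0L) next
    L <- regions$end[r] - regions$start[r]
    tl <- tads$end[t_idx] - tads$start[t_idx]
    if (any(tl > L)) {
      abort(paste0("Region ", regions$region_id[r],
                   " is shorter than its longest TAD."))
    }
    in_r <- interactions$bait_chrom == regions$chrom[r] &
      bait_mid >= regions$start[r] & bait_mid < regions$end[r] &
      interactions$oe_chrom == regions$chrom[r] &
      oe_mid >= regions$start[r] & oe_mid < regions$end[r]
    if (!any(in_r)) {
      per_region[[length(per_region) + 1]] <-
        list(m1 = numeric(), m2 = numeric(), s = tads$start[t_idx] - regions$start[r],
             len = tl, L = L)
      next
    }
    per_region[[length(per_region) + 1]] <- list(
      m1 = bait_mid[in_r] - regions$start[r],
      m2 = oe_mid[in_r] - regions$start[r],
      s = tads$start[t_idx] - regions$start[r],
      len = tl, L = L
    )
  }

  count_within <- function(pr, offset) {
    if (length(pr$m1) == 0L) return(0L)
    s_shift <- (pr$s + offset) %% pr$L
    lenm <- matrix(pr$len, nrow = length(pr$m1), ncol = length(pr$len),
                   byrow = TRUE)
    in1 <- (outer(pr$m1, s_shift, "-") %% pr$L) < lenm
    in2 <- (outer(pr$m2, s_shift, "-") %% pr$L) < lenm
    sum(rowSums(in1 & in2) > 0)
  }

  observed <- sum(vapply(per_region, function(pr) {
    count_within(pr, rep(0, length(pr$s)))
  }, numeric(1)))

  if (length(per_region) == 0L) {
    # No TAD lies inside any region: the statistic is identically zero.
    return(perm_test_result(0, rep(0, n_perms), seed = rng_seed %||% NA_integer_))
  }

  null_values <- with_seed(rng_seed, {
    vapply(seq_len(n_perms), function(i) {
      sum(vapply(per_region, function(pr) {
        count_within(pr, runif_pos(length(pr$s), pr$L))
      }, numeric(1)))
    }, numeric(1))
  })
  perm_test_result(observed, null_values, seed = rng_seed %||% NA_integer_)
}
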