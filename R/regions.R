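#' Per-cancer risk regions from flank-extended index variants
#'
#' Each index variant is extended by `flank` bp on either side (the variant
#' base itself included, i.e. `[pos - flank, pos + flank + 1)`), clamped to
#' the chromosome, and the per-cancer intervals are merged. Non-index (LD
#' proxy) variants do not seed regions.
#'
#' @param variants Variant tibble; only rows with `is_index = TRUE` are used.
#' @param assembly A [genome_assembly()].
#' @param flank Extension in bp on each side (default 500 kb).
#' @return Named list (one element per cancer present) of merged interval
#'   tibbles.
#' @export
build_cancer_regions <- function(variants, assembly, flank = 500000) {
  if (!is.numeric(flank) || length(flank) != 1L || is.na(flank) || flank <= 0) {
    abort("`flank` must be a single positive number.")
  }
  check_chroms(variants$chrom, assembly, "variant")
  idx <- filter(variants, .data$is_index)
  cancers <- sort(unique(idx$cancer))
  out <- lapply(cancers, function(cc) {
    v <- filter(idx, .data$cancer == cc)
    len <- chrom_length(assembly, v$chrom)
    iv <- genomic_intervals(v$chrom,
                            pmax(0, v$pos - flank),
                            pmin(len, v$pos + flank + 1))
    merge_intervals(iv)
  })
  names(out) <- cancers
  out
}

#' Multi-cancer risk regions
#'
#' A multi-cancer risk region is a maximal genomic segment where the extended
#' risk intervals of at least `min_cancers` distinct cancers overlap.
#' Qualifying segments that touch are fused into one region even if the
#' contributing cancer pair changes along the segment; the region's cancer set
#' is every cancer whose extended interval overlaps it. Regions are numbered
#' 1..N in genome order (assembly chromosome order, then start).
#'
#' @param per_cancer_intervals Named list of merged interval tibbles, as from
#'   [build_cancer_regions()].
#' @param assembly A [genome_assembly()] (fixes the chromosome order used for
#'   region numbering).
#' @param min_cancers Minimum number of overlapping cancers (default 2).
#' @return Tibble with `region_id`, `chrom`, `start`, `end` and list-column
#'   `cancers`.
#' @export
build_mhdcr_regions <- function(per_cancer_intervals, assembly,
                                min_cancers = 2) {
  segs <- coverage_segments(per_cancer_intervals, min_cancers)
  if (nrow(segs) == 0L) {
    return(tibble(region_id = integer(), chrom = character(),
                  start = numeric(), end = numeric(), cancers = list()))
  }
  segs <- segs[order(chrom_rank(segs$chrom, assembly), segs$start), ]
  segs$region_id <- seq_len(nrow(segs))
  segs <- rename(segs, cancers = "labels")
  segs[, c("region_id", "chrom", "start", "end", "cancers")]
}

#' Count independent GWAS signals per region and cancer
#'
#' For every region and cancer, counts the distinct `signal_id`s whose index
#' variant position falls inside the region interval.
#'
#' @param regions Region tibble from [build_mhdcr_regions()].
#' @param variants Variant tibble carrying `signal_id` and `is_index`.
#' @return `regions` with an added list-column `signal_counts` (named integer
#'   vector per region, one entry per cancer with >= 1 signal). The long form
#'   is available via [signal_count_table()].
#' @export
count_signals <- function(regions, variants) {
  long <- signal_count_table(regions, variants)
  regions$signal_counts <- lapply(regions$region_id, function(rid) {
    rows <- long[long$region_id == rid, ]
    stats::setNames(as.integer(rows$n_signals), rows$cancer)
  })
  regions
}

#' Long-form signal counts per (region, cancer)
#'
#' @inheritParams count_signals
#' @return Tibble `region_id`, `cancer`, `n_signals` (only non-zero rows).
#' @export
signal_count_table <- function(regions, variants) {
  idx <- filter(variants, .data$is_index)
  if (nrow(regions) == 0L || nrow(idx) == 0L) {
    return(tibble(region_id = integer(), cancer = character(),
                  n_signals = integer()))
  }
  hits <- GenomicRanges::findOverlaps(
    iv_to_gr(tibble(chrom = idx$chrom, start = idx$pos, end = idx$pos + 1)),
    iv_to_gr(regions)
  )
  tibble(
    region_id = regions$region_id[S4Vectors::subjectHits(hits)],
    cancer = idx$cancer[S4Vectors::queryHits(hits)],
    signal_id = idx$signal_id[S4Vectors::queryHits(hits)]
  ) |>
    distinct() |>
    group_by(.data$region_id, .data$cancer) |>
    summarise(n_signals = dplyr::n_distinct(.data$signal_id), .groups = "drop")
}

#' Summarise regions by cancer combination
#'
#' @param regions Region tibble with list-column `cancers`.
#' @return List with `by_combination` (tibble `combination`, `n`, labels
#'   joined with `+` in sorted order) and `by_cardinality` (tibble
#'   `n_cancers`, `n`).
#' @export
combination_summary <- function(regions) {
  combo <- vapply(regions$cancers, function(x) paste(sort(x), collapse = "+"),
                  character(1))
  card <- lengths(regions$cancers)
  list(
    by_combination = tibble(combination = combo) |>
      group_by(.data$combination) |>
      summarise(n = dplyr::n(), .groups = "drop") |>
      arrange(dplyr::desc(.data$n), .data$combination),
    by_cardinality = tibble(n_cancers = card) |>
      group_by(.data$n_cancers) |>
      summarise(n = dplyr::n(), .groups = "drop") |>
      arrange(.data$n_cancers)
  )
}

#' Write regions as BED plus a sidecar summary TSV
#'
#' The BED file carries `region_id` in the name column; the sidecar lists the
#' cancer set and per-cancer signal counts per region.
#'
#' @param regions Region tibble, optionally after [count_signals()].
#' @param bed_path Output BED path.
#' @param summary_path Optional output TSV path.
#' @return `bed_path`, invisibly.
#' @export
write_regions <- function(regions, bed_path, summary_path = NULL) {
  bed <- tibble(chrom = regions$chrom, start = regions$start,
                end = regions$end, name = as.character(regions$region_id))
  write_bed(bed, bed_path)
  if (!is.null(summary_path)) {
    fmt_counts <- function(x) {
      if (is.null(x) || length(x) == 0) return("")
      paste(paste0(names(x), "=", x), collapse = ",")
    }
    df <- tibble(
      region_id = regions$region_id,
      chrom = regions$chrom, start = regions$start, end = regions$end,
      cancers = vapply(regions$cancers, paste, character(1), collapse = ","),
      signal_counts = if ("signal_counts" %in% names(regions)) {
        vapply(regions$signal_counts, fmt_counts, character(1))
      } else ""
    )
    readr::write_tsv(df, summary_path)
  }
  invisible(bed_path)
}
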