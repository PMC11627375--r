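#' Genomic intervals
#'
#' Intervals are plain tibbles with columns `chrom`, `start`, `end` using
#' 0-based half-open coordinates (`start` inclusive, `end` exclusive), the BED
#' convention. Conversion to/from the 1-based closed `GRanges` representation
#' is internal; all user-visible coordinates stay 0-based half-open.
#'
#' @param chrom Character vector of chromosome names.
#' @param start,end Numeric vectors, 0-based half-open (`start < end`).
#' @param assembly Optional [genome_assembly()]; when given, chromosomes must
#'   exist and `end` must not exceed the chromosome length.
#' @return A tibble with columns `chrom`, `start`, `end`.
#' @export
genomic_intervals <- function(chrom, start, end, assembly = NULL) {
  out <- tibble(chrom = as.character(chrom),
                start = as.numeric(start), end = as.numeric(end))
  if (nrow(out) && any(is.na(out$start) | is.na(out$end) | out$start < 0 |
                       out$start >= out$end)) {
    abort("Intervals require 0 <= start < end.")
  }
  if (!is.null(assembly) && nrow(out)) {
    check_chroms(out$chrom, assembly, "interval")
    if (any(out$end > chrom_length(assembly, out$chrom))) {
      abort("Interval end exceeds chromosome length.")
    }
  }
  out
}

# tibble (0-based half-open) <-> GRanges (1-based closed)
iv_to_gr <- function(iv) {
  GenomicRanges::GRanges(
    seqnames = iv$chrom,
    ranges = IRanges::IRanges(start = iv$start + 1, end = iv$end)
  )
}

gr_to_iv <- function(gr) {
  tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1,
    end = as.numeric(GenomicRanges::end(gr))
  )
}

#' Merge overlapping and book-ended intervals
#'
#' Collapses a set of intervals into the minimal sorted set of disjoint
#' intervals covering the same bases. Book-ended half-open intervals (e.g.
#' `[100,200)` and `[200,300)`) merge, matching `bedtools merge` defaults.
#'
#' @param intervals Tibble with `chrom`, `start`, `end` (0-based half-open).
#' @return Sorted tibble of disjoint, non-adjacent intervals.
#' @examples
#' merge_intervals(genomic_intervals("chr1", c(100, 150), c(200, 300)))
#' @export
merge_intervals <- function(intervals) {
  if (nrow(intervals) == 0L) {
    return(genomic_intervals(character(), numeric(), numeric()))
  }
  merged <- GenomicRanges::reduce(iv_to_gr(intervals))
  out <- gr_to_iv(merged)
  arrange(out, .data$chrom, .data$start)
}

#' Maximal segments covered by at least `min_labels` labelled interval sets
#'
#' Given one merged interval set per label, returns the maximal genomic
#' segments where at least `min_labels` distinct labels cover every base.
#' Contiguous or book-ended qualifying segments are fused. Each segment
#' carries the set of all labels whose intervals overlap it (which can exceed
#' the labels covering any single base).
#'
#' @param interval_sets Named list of interval tibbles, one per label; each
#'   should already be merged (see [merge_intervals()]).
#' @param min_labels Minimum number of distinct labels required (>= 1).
#' @return Tibble with `chrom`, `start`, `end` and a list-column `labels`
#'   (character vector per segment, sorted).
#' @export
coverage_segments <- function(interval_sets, min_labels) {
  if (!is_count(min_labels) || min_labels < 1) {
    abort("`min_labels` must be an integer >= 1.")
  }
  interval_sets <- interval_sets[vapply(interval_sets, nrow, 1L) > 0]
  if (length(interval_sets) < min_labels) {
    return(tibble(chrom = character(), start = numeric(), end = numeric(),
                  labels = list()))
  }
  labels <- names(interval_sets)
  all_iv <- bind_rows(interval_sets, .id = "label")
  gr <- iv_to_gr(all_iv)
  S4Vectors::mcols(gr)$label <- all_iv$label

  bins <- GenomicRanges::disjoin(gr)
  hits <- GenomicRanges::findOverlaps(bins, gr)
  depth <- tapply(gr$label[S4Vectors::subjectHits(hits)],
                  S4Vectors::queryHits(hits),
                  function(x) length(unique(x)))
  keep_idx <- as.integer(names(depth))[depth >= min_labels]
  if (length(keep_idx) == 0L) {
    return(tibble(chrom = character(), start = numeric(), end = numeric(),
                  labels = list()))
  }
  segs <- GenomicRanges::reduce(bins[keep_idx])
  seg_hits <- GenomicRanges::findOverlaps(segs, gr)
  seg_labels <- lapply(seq_along(segs), function(i) {
    sort(unique(gr$label[S4Vectors::subjectHits(seg_hits)[
      S4Vectors::queryHits(seg_hits) == i]]))
  })
  out <- gr_to_iv(segs)
  out$labels <- seg_labels
  arrange(out, .data$chrom, .data$start)
}

#' Read a BED3/BED4/BED6 file as intervals
#'
#' @param path Path to a BED file (no header).
#' @param assembly Optional [genome_assembly()] for validation.
#' @return Tibble with `chrom`, `start`, `end`, plus `name` (and `score`,
#'   `strand`) when present in the file.
#' @export
read_bed <- function(path, assembly = NULL) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          colClasses = "character")
  names(df)[1:3] <- c("chrom", "start", "end")
  extra <- c("name", "score", "strand")
  if (ncol(df) > 3) {
    names(df)[4:min(ncol(df), 6)] <- extra[seq_len(min(ncol(df), 6) - 3)]
  }
  out <- as_tibble(df[, seq_len(min(ncol(df), 6)), drop = FALSE])
  out$start <- as.numeric(out$start)
  out$end <- as.numeric(out$end)
  if ("score" %in% names(out)) out$score <- as.numeric(out$score)
  genomic_intervals(out$chrom, out$start, out$end, assembly)
  if (!is.null(assembly)) check_chroms(out$chrom, assembly, "BED record")
  out
}

#' Write intervals as BED
#'
#' Coordinates are written exactly as stored (0-based half-open), BED3 by
#' default, BED4/BED6 when `name` / `score` + `strand` columns are present.
#'
#' @param intervals Interval tibble; optional columns `name`, `score`, `strand`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  cols <- c("chrom", "start", "end")
  for (extra in c("name", "score", "strand")) {
    if (extra %in% names(intervals)) cols <- c(cols, extra) else break
  }
  df <- as.data.frame(intervals[, cols, drop = FALSE])
  df$start <- format(df$start, scientific = FALSE, trim = TRUE)
  df$end <- format(df$end, scientific = FALSE, trim = TRUE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
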