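#' Default active ChromHMM states
#'
#' Promoter- and enhancer-class labels counted as evidence of regulatory
#' activity (18-state EpiMap-style model naming). Override via the
#' `active_states` argument of [chromhmm_support()].
#'
#' @return Character vector of state labels.
#' @export
active_chromhmm_states <- function() {
  c("TssA", "TssFlnk", "TssFlnkU", "TssFlnkD",
    "EnhA1", "EnhA2", "EnhG1", "EnhG2", "EnhWk")
}

#' Classify variant location relative to gene models
#'
#' For every (variant, gene) pair in genomic contact, assigns exactly one
#' class with the per-gene precedence exon > promoter > intron: `exonic` when
#' the variant base falls in any exon of the gene, else `promoter` when it
#' lies within TSS +/- `promoter_flank` (boundaries inclusive), else
#' `intronic` when inside the gene span. A variant may be, e.g., promoter of
#' one gene and intronic of another; a variant with no gene context at all is
#' intergenic (it simply has no row here — see [summarize_location()]).
#'
#' @param variants Variant tibble.
#' @param gm A [gene_models()] object.
#' @param promoter_flank Promoter half-width in bp (default 2000).
#' @return Tibble `variant_id`, `gene_id`, `location_class` (one row per
#'   variant-gene contact).
#' @export
classify_location <- function(variants, gm, promoter_flank = 2000) {
  if (nrow(variants) == 0L) {
    return(tibble(variant_id = character(), gene_id = character(),
                  location_class = character()))
  }
  vgr <- iv_to_gr(tibble(chrom = variants$chrom, start = variants$pos,
                         end = variants$pos + 1))
  g <- gm$genes
  span_hits <- GenomicRanges::findOverlaps(
    vgr, iv_to_gr(tibble(chrom = g$chrom, start = g$start, end = g$end)))
  prom <- promoter_intervals(gm, flank = promoter_flank)
  prom_hits <- GenomicRanges::findOverlaps(vgr, iv_to_gr(prom))
  exon_hits <- GenomicRanges::findOverlaps(vgr, iv_to_gr(gm$exons))

  pairs <- bind_rows(
    tibble(v = S4Vectors::queryHits(span_hits),
           gene_id = g$gene_id[S4Vectors::subjectHits(span_hits)],
           cls = "intronic"),
    tibble(v = S4Vectors::queryHits(prom_hits),
           gene_id = prom$gene_id[S4Vectors::subjectHits(prom_hits)],
           cls = "promoter"),
    tibble(v = S4Vectors::queryHits(exon_hits),
           gene_id = gm$exons$gene_id[S4Vectors::subjectHits(exon_hits)],
           cls = "exonic")
  )
  if (nrow(pairs) == 0L) {
    return(tibble(variant_id = character(), gene_id = character(),
                  location_class = character()))
  }
  rank <- c(exonic = 1L, promoter = 2L, intronic = 3L)
  pairs |>
    mutate(priority = rank[.data$cls]) |>
    group_by(.data$v, .data$gene_id) |>
    summarise(location_class = .data$cls[which.min(.data$priority)],
              .groups = "drop") |>
    mutate(variant_id = variants$variant_id[.data$v]) |>
    select("variant_id", "gene_id", "location_class") |>
    arrange(.data$variant_id, .data$gene_id)
}

#' One summary location class per variant
#'
#' Collapses per-gene classes into a single label per variant with the
#' precedence exonic > promoter > intronic > intergenic (the convention used
#' for class-breakdown tallies: a variant exonic for any gene counts as
#' exonic, etc.).
#'
#' @param variants Variant tibble.
#' @param location Long classification from [classify_location()].
#' @return Tibble `variant_id`, `location_summary`; every input variant gets
#'   exactly one row, intergenic when it has no gene context.
#' @export
summarize_location <- function(variants, location) {
  rank <- c(exonic = 1L, promoter = 2L, intronic = 3L)
  if (nrow(location) == 0L) {
    return(tibble(variant_id = unique(variants$variant_id),
                  location_summary = "intergenic"))
  }
  best <- location |>
    group_by(.data$variant_id) |>
    summarise(location_summary = names(rank)[min(rank[.data$location_class])],
              .groups = "drop")
  tibble(variant_id = unique(variants$variant_id)) |>
    left_join(best, by = "variant_id") |>
    mutate(location_summary = ifelse(is.na(.data$location_summary),
                                     "intergenic", .data$location_summary))
}

#' Splice-altering verdict for intronic variants
#'
#' A variant qualifies when its SpliceAI delta score is at least 0.2 (the
#' probability-like threshold, boundary inclusive) OR the absolute MaxEntScan
#' maximum-entropy score exceeds 0. Missing scores never qualify.
#'
#' @param spliceai_delta Numeric vector in `[0, 1]`, `NA` allowed.
#' @param maxentscan Numeric vector, `NA` allowed.
#' @param spliceai_threshold SpliceAI delta cutoff (default 0.2, inclusive).
#' @return Logical vector.
#' @export
is_splice_altering <- function(spliceai_delta, maxentscan,
                               spliceai_threshold = 0.2) {
  (!is.na(spliceai_delta) & spliceai_delta >= spliceai_threshold) |
    (!is.na(maxentscan) & abs(maxentscan) > 0)
}

#' Regulatory verdict from RegulomeDB probability
#'
#' A variant is called potentially regulatory when its RegulomeDB probability
#' is strictly greater than 0.55 (the median of the genome-wide score
#' distribution); a probability of exactly 0.55 does not qualify. Missing
#' probabilities never qualify.
#'
#' @param regulome_probability Numeric vector in `[0, 1]`, `NA` allowed.
#' @param threshold Strict lower cutoff (default 0.55).
#' @param warn_missing Emit a message when probabilities are missing.
#' @return Logical vector.
#' @export
is_regulatory <- function(regulome_probability, threshold = 0.55,
                          warn_missing = FALSE) {
  if (warn_missing && anyNA(regulome_probability)) {
    inform(paste0(sum(is.na(regulome_probability)),
                  " variant(s) lack a RegulomeDB probability; treated as",
                  " non-regulatory."))
  }
  !is.na(regulome_probability) & regulome_probability > threshold
}

#' Coding evidence category from VEP consequence class
#'
#' Frameshift, missense, synonymous and UTR consequences are retained as
#' evidence categories for gene calling; any other (or absent) consequence
#' yields `NA`.
#'
#' @param vep_class Character vector of consequence classes.
#' @return Character vector: the category, or `NA` for non-qualifying classes.
#' @export
coding_evidence <- function(vep_class) {
  keep <- c("frameshift", "missense", "synonymous", "utr5", "utr3")
  ifelse(vep_class %in% keep, vep_class, NA_character_)
}

#' ChromHMM support for a variant
#'
#' TRUE when any relevant biosample assigns the variant an active-class
#' chromatin state (promoter/enhancer states by default).
#'
#' @param chromhmm Long tibble `variant_id`, `biosample`, `state`.
#' @param variant_ids Variants to assess.
#' @param relevant_biosamples Biosample labels to consider; `NULL` = all.
#' @param active_states Labels counted as active
#'   (default [active_chromhmm_states()]).
#' @return Named logical vector over `variant_ids`.
#' @export
chromhmm_support <- function(chromhmm, variant_ids,
                             relevant_biosamples = NULL,
                             active_states = active_chromhmm_states()) {
  hh <- chromhmm
  if (!is.null(relevant_biosamples)) {
    hh <- filter(hh, .data$biosample %in% relevant_biosamples)
  }
  hh <- filter(hh, .data$state %in% active_states)
  stats::setNames(variant_ids %in% hh$variant_id, variant_ids)
}
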