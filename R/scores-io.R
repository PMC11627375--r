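#' Read a per-variant functional score table
#'
#' Tab-separated with header. Fixed columns: `variant_id`, `vep_class`,
#' `spliceai_delta`, `maxentscan`, `regulome_rank`, `regulome_probability`
#' (all but `variant_id` optional; missing values `NA`). ChromHMM states are
#' accepted in either layout:
#'
#' * wide — one column per biosample named `chromhmm_<biosample>`;
#' * long — columns `biosample` and `chromhmm_state`, one row per
#'   (variant, biosample), fixed columns repeated.
#'
#' @param path Path to the TSV file.
#' @return List of class `annotation_scores`: `scores` (tibble, one row per
#'   variant) and `chromhmm` (long tibble `variant_id`, `biosample`, `state`).
#' @export
read_scores <- function(path) {
  df <- as_tibble(utils::read.table(path, sep = "\t", header = TRUE,
                                    colClasses = "character",
                                    comment.char = "", na.strings = "NA"))
  if (!"variant_id" %in% names(df)) {
    abort("Score table needs a `variant_id` column.")
  }
  long_layout <- all(c("biosample", "chromhmm_state") %in% names(df))
  wide_cols <- grep("^chromhmm_", names(df), value = TRUE)
  wide_cols <- setdiff(wide_cols, "chromhmm_state")

  num <- function(x) suppressWarnings(as.numeric(x))
  fixed <- c("vep_class", "spliceai_delta", "maxentscan",
             "regulome_rank", "regulome_probability")
  base <- df
  if (long_layout) {
    base <- distinct(df[, setdiff(names(df), c("biosample", "chromhmm_state")),
                        drop = FALSE])
  }
  scores <- tibble(
    variant_id = base$variant_id,
    vep_class = if ("vep_class" %in% names(base)) {
      ifelse(is.na(base$vep_class), "none", base$vep_class)
    } else "none",
    spliceai_delta = if ("spliceai_delta" %in% names(base)) num(base$spliceai_delta) else NA_real_,
    maxentscan = if ("maxentscan" %in% names(base)) num(base$maxentscan) else NA_real_,
    regulome_rank = if ("regulome_rank" %in% names(base)) base$regulome_rank else NA_character_,
    regulome_probability = if ("regulome_probability" %in% names(base)) num(base$regulome_probability) else NA_real_
  )
  if (anyDuplicated(scores$variant_id)) {
    abort("Score table has conflicting duplicate rows for one variant.")
  }
  bad <- !is.na(scores$spliceai_delta) &
    (scores$spliceai_delta < 0 | scores$spliceai_delta > 1)
  bad <- bad | (!is.na(scores$regulome_probability) &
                  (scores$regulome_probability < 0 | scores$regulome_probability > 1))
  if (any(bad)) abort("SpliceAI delta and RegulomeDB probability must lie in [0, 1].")

  if (long_layout) {
    chromhmm <- tibble(variant_id = df$variant_id,
                       biosample = df$biosample,
                       state = df$chromhmm_state) |>
      filter(!is.na(.data$state))
  } else if (length(wide_cols)) {
    chromhmm <- df[, c("variant_id", wide_cols)] |>
      tidyr::pivot_longer(dplyr::all_of(wide_cols),
                          names_to = "biosample", values_to = "state") |>
      mutate(biosample = sub("^chromhmm_", "", .data$biosample)) |>
      filter(!is.na(.data$state))
  } else {
    chromhmm <- tibble(variant_id = character(), biosample = character(),
                       state = character())
  }
  structure(list(scores = scores, chromhmm = chromhmm),
            class = "annotation_scores")
}

#' Write a score table (wide ChromHMM layout)
#'
#' @param annotation An `annotation_scores` list (as from [read_scores()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scores <- function(annotation, path) {
  out <- annotation$scores
  if (nrow(annotation$chromhmm)) {
    wide <- annotation$chromhmm |>
      mutate(biosample = paste0("chromhmm_", .data$biosample)) |>
      tidyr::pivot_wider(names_from = "biosample", values_from = "state")
    out <- left_join(out, wide, by = "variant_id")
  }
  readr::write_tsv(out, path, na = "NA")
  invisible(path)
}
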