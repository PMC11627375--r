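#' Read a GWAS variant table
#'
#' Tab-separated file with a header containing at least `variant_id`, `chrom`,
#' `pos` and `cancer`; optional columns `signal_id`, `is_index`, `r2`.
#' Positions are 0-based; a position equal to the chromosome length is out of
#' range. Unknown chromosomes and unknown trait labels are errors, never
#' silently dropped (silent loss would corrupt permutation counts downstream).
#'
#' @param path Path to the TSV file.
#' @param assembly A [genome_assembly()] used to validate chromosomes and
#'   positions.
#' @param allowed_cancers Character vector of allowed trait labels; defaults
#'   to the four hormone-dependent cancers. Pass other labels to analyse
#'   other trait sets with the same machinery.
#' @return Tibble with columns `variant_id`, `chrom`, `pos`, `cancer`,
#'   `signal_id`, `is_index`, `r2`, preserving file order.
#' @export
read_variants <- function(path, assembly,
                          allowed_cancers = hdc_cancers()) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = "character", comment.char = "")
  required <- c("variant_id", "chrom", "pos", "cancer")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    abort(paste0("Variant file is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  pos <- suppressWarnings(as.numeric(df$pos))
  bad <- which(is.na(pos) | pos < 0 | pos != floor(pos))
  if (length(bad)) {
    abort(paste0("Malformed position at line ", bad[1] + 1,
                 " of ", path, " (value: '", df$pos[bad[1]], "')."))
  }
  unknown <- setdiff(unique(df$cancer), allowed_cancers)
  if (length(unknown)) {
    abort(paste0("Unknown trait label(s): ", paste(unknown, collapse = ", "),
                 ". Allowed: ", paste(allowed_cancers, collapse = ", "), "."))
  }
  check_chroms(df$chrom, assembly, "variant")
  len <- chrom_length(assembly, df$chrom)
  oob <- which(pos >= len)
  if (length(oob)) {
    abort(paste0("Position out of range at line ", oob[1] + 1,
                 ": pos ", pos[oob[1]], " on ", df$chrom[oob[1]],
                 " (length ", len[oob[1]], ", 0-based pos must be < length)."))
  }
  tibble(
    variant_id = df$variant_id,
    chrom = df$chrom,
    pos = pos,
    cancer = df$cancer,
    signal_id = if ("signal_id" %in% names(df)) df$signal_id else df$variant_id,
    is_index = if ("is_index" %in% names(df)) {
      toupper(df$is_index) %in% c("TRUE", "T", "1", "YES")
    } else TRUE,
    r2 = if ("r2" %in% names(df)) suppressWarnings(as.numeric(df$r2)) else NA_real_
  )
}

#' Write a GWAS variant table
#'
#' Inverse of [read_variants()]; a written file re-read against the same
#' assembly reproduces the input tibble.
#'
#' @param variants Variant tibble as returned by [read_variants()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_variants <- function(variants, path) {
  df <- as.data.frame(variants[, c("variant_id", "chrom", "pos", "cancer",
                                   "signal_id", "is_index", "r2")])
  df$pos <- format(df$pos, scientific = FALSE, trim = TRUE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "NA")
  invisible(path)
}
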