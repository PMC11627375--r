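#' Genome assembly: named chromosomes with lengths
#'
#' A minimal assembly descriptor binding chromosome names to their lengths in
#' base pairs. All genomic coordinates in the package are 0-based, half-open
#' and validated against an assembly where one is supplied.
#'
#' @param chromosomes Character vector of chromosome names (unique).
#' @param lengths Integer-like vector of chromosome lengths in bp (> 0).
#' @param name Optional text label for the assembly.
#'
#' @return A tibble of class `genome_assembly` with columns `chrom`, `length`
#'   and attribute `assembly_name`.
#' @examples
#' genome_assembly(c("chr1", "chr2"), c(2e6, 1e6))
#' @export
genome_assembly <- function(chromosomes, lengths, name = "custom") {
  chromosomes <- as.character(chromosomes)
  lengths <- as.numeric(lengths)
  if (length(chromosomes) != length(lengths)) {
    abort("`chromosomes` and `lengths` must have the same length.")
  }
  if (anyDuplicated(chromosomes)) {
    abort("Chromosome names must be unique.")
  }
  if (any(is.na(lengths)) || any(lengths <= 0) || any(lengths != floor(lengths))) {
    abort("Chromosome lengths must be positive integers.")
  }
  out <- tibble(chrom = chromosomes, length = lengths)
  attr(out, "assembly_name") <- name
  class(out) <- c("genome_assembly", class(out))
  out
}

#' Read a UCSC-style chrom.sizes file
#'
#' Two tab-separated columns (chromosome name, length in bp), no header.
#'
#' @param path Path to the chrom.sizes file.
#' @param name Assembly label, defaults to the file base name.
#' @return A [genome_assembly()].
#' @export
read_chrom_sizes <- function(path, name = NULL) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "length"),
                          colClasses = c("character", "numeric"))
  genome_assembly(df$chrom, df$length,
                  name = name %||% sub("\\.sizes$", "", basename(path)))
}

#' Write a chrom.sizes file
#'
#' @param assembly A [genome_assembly()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_chrom_sizes <- function(assembly, path) {
  utils::write.table(as.data.frame(assembly[, c("chrom", "length")]),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

chrom_length <- function(assembly, chrom) {
  assembly$length[match(chrom, assembly$chrom)]
}

check_chroms <- function(chrom, assembly, what = "record") {
  unknown <- setdiff(unique(chrom), assembly$chrom)
  if (length(unknown)) {
    abort(paste0("Unknown chromosome(s) for ", what, ": ",
                 paste(unknown, collapse = ", "),
                 ". Assembly has: ", paste(assembly$chrom, collapse = ", "), "."))
  }
  invisible(TRUE)
}

# Order chromosomes as in the assembly (genome order for region numbering).
chrom_rank <- function(chrom, assembly) {
  match(chrom, assembly$chrom)
}
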