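#' Gene models
#'
#' A `gene_models` object bundles a gene table and an exon table. The TSS is
#' derived from the exons respecting strand (5'-most exon boundary: first base
#' of the first exon on `+`, last base of the last exon on `-`), stored as a
#' 0-based position. Promoters are defined as TSS +/- `promoter_flank`
#' (default 2 kb), inclusive at both boundaries.
#'
#' @param genes Tibble with `gene_id`, `name`, `biotype` (one of
#'   `protein_coding`, `lncRNA`, `other`), `chrom`, `strand` (`+`/`-`).
#' @param exons Tibble with `gene_id`, `chrom`, `start`, `end`
#'   (0-based half-open); at least one exon per gene, on the gene's chromosome.
#' @return An object of class `gene_models`: list with tibbles `genes`
#'   (gaining `start`, `end`, `tss`) and `exons` (sorted).
#' @export
gene_models <- function(genes, exons) {
  stopifnot(all(c("gene_id", "name", "biotype", "chrom", "strand") %in% names(genes)),
            all(c("gene_id", "chrom", "start", "end") %in% names(exons)))
  if (!all(genes$strand %in% c("+", "-"))) abort("Strand must be '+' or '-'.")
  if (!all(genes$gene_id %in% exons$gene_id)) {
    abort("Every gene needs at least one exon.")
  }
  bad_chrom <- inner_join(exons, genes, by = "gene_id",
                          suffix = c("", ".gene")) |>
    filter(.data$chrom != .data$chrom.gene)
  if (nrow(bad_chrom)) abort("Exons must lie on their gene's chromosome.")
  exons <- arrange(exons, .data$gene_id, .data$start)
  span <- exons |>
    group_by(.data$gene_id) |>
    summarise(start = min(.data$start), end = max(.data$end), .groups = "drop")
  genes <- genes |>
    select(-dplyr::any_of(c("start", "end", "tss"))) |>
    left_join(span, by = "gene_id") |>
    mutate(tss = ifelse(.data$strand == "+", .data$start, .data$end - 1))
  structure(list(genes = as_tibble(genes), exons = as_tibble(exons)),
            class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat("gene_models: ", nrow(x$genes), " genes (",
      sum(x$genes$biotype == "protein_coding"), " protein-coding, ",
      sum(x$genes$biotype == "lncRNA"), " lncRNA), ",
      nrow(x$exons), " exons\n", sep = "")
  invisible(x)
}

#' Promoter intervals for gene models
#'
#' Promoter = TSS +/- `flank`, inclusive at both ends, i.e. the half-open
#' interval `[tss - flank, tss + flank + 1)`, clamped at chromosome start
#' (and at chromosome end when an assembly is given).
#'
#' @param gm A [gene_models()] object.
#' @param flank Promoter half-width in bp (default 2000).
#' @param assembly Optional [genome_assembly()] for end clamping.
#' @return Tibble with `gene_id`, `chrom`, `start`, `end`.
#' @export
promoter_intervals <- function(gm, flank = 2000, assembly = NULL) {
  g <- gm$genes
  out <- tibble(
    gene_id = g$gene_id,
    chrom = g$chrom,
    start = pmax(0, g$tss - flank),
    end = g$tss + flank + 1
  )
  if (!is.null(assembly)) {
    out$end <- pmin(out$end, chrom_length(assembly, out$chrom))
  }
  out
}

#' Read gene models from a GFF3 file
#'
#' Expects `gene` and `exon` features carrying `gene_id` and (optionally)
#' `gene_name` and `gene_biotype` attributes, as written by
#' [write_gene_models_gff3()] or extracted from GENCODE-style annotation.
#'
#' @param path Path to the GFF3 file.
#' @return A [gene_models()] object.
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  md <- S4Vectors::mcols(gr)
  type <- as.character(md$type)
  get_attr <- function(field, default) {
    if (field %in% names(md)) as.character(md[[field]]) else default
  }
  gene_id <- get_attr("gene_id", get_attr("ID", NA_character_))
  is_gene <- type == "gene"
  genes <- tibble(
    gene_id = gene_id[is_gene],
    name = get_attr("gene_name", gene_id)[is_gene],
    biotype = get_attr("gene_biotype", rep("protein_coding", length(gr)))[is_gene],
    chrom = as.character(GenomicRanges::seqnames(gr))[is_gene],
    strand = as.character(GenomicRanges::strand(gr))[is_gene]
  )
  is_exon <- type == "exon"
  exons <- tibble(
    gene_id = gene_id[is_exon],
    chrom = as.character(GenomicRanges::seqnames(gr))[is_exon],
    start = GenomicRanges::start(gr)[is_exon] - 1,
    end = as.numeric(GenomicRanges::end(gr))[is_exon]
  )
  gene_models(genes, exons)
}

#' Write gene models as GFF3
#'
#' @param gm A [gene_models()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_models_gff3 <- function(gm, path) {
  g <- gm$genes
  e <- left_join(gm$exons,
                 g[, c("gene_id", "strand", "name", "biotype")],
                 by = "gene_id")
  fmt <- function(chrom, type, start, end, strand, attrs) {
    paste(chrom, "pleiogene", type,
          format(start + 1, scientific = FALSE, trim = TRUE),
          format(end, scientific = FALSE, trim = TRUE),
          ".", strand, ".", attrs, sep = "\t")
  }
  gene_lines <- fmt(g$chrom, "gene", g$start, g$end, g$strand,
                    paste0("ID=", g$gene_id, ";gene_id=", g$gene_id,
                           ";gene_name=", g$name, ";gene_biotype=", g$biotype))
  exon_lines <- fmt(e$chrom, "exon", e$start, e$end, e$strand,
                    paste0("Parent=", e$gene_id, ";gene_id=", e$gene_id,
                           ";gene_name=", e$name, ";gene_biotype=", e$biotype))
  writeLines(c("##gff-version 3", gene_lines, exon_lines), path)
  invisible(path)
}
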