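#' Default pipeline parameters
#'
#' Every printed threshold of the analysis in one place: the 100 kb cluster
#' window, 0.5 Mb region flank, minimum of two cancers per region, promoter
#' half-width of 2 kb, CHiCAGO confidence cutoff of 5, and the permutation
#' counts of the three resampling stages.
#'
#' @param max_gap Cluster gap in bp.
#' @param flank Region extension in bp.
#' @param min_cancers Minimum cancers per region / candidate.
#' @param promoter_flank Promoter half-width in bp.
#' @param min_score Interaction score cutoff.
#' @param n_perms_cluster,n_perms_tad,n_perms_matched Permutation counts.
#' @param seed Master seed for the permutation stages.
#' @return Named list of parameters.
#' @export
pipeline_params <- function(max_gap = 100000, flank = 500000,
                            min_cancers = 2, promoter_flank = 2000,
                            min_score = 5, n_perms_cluster = 10000,
                            n_perms_tad = 2000, n_perms_matched = 10000,
                            seed = 1) {
  list(max_gap = max_gap, flank = flank, min_cancers = min_cancers,
       promoter_flank = promoter_flank, min_score = min_score,
       n_perms_cluster = n_perms_cluster, n_perms_tad = n_perms_tad,
       n_perms_matched = n_perms_matched, seed = seed)
}

#' Write a dataset to disk in the pipeline's standard formats
#'
#' chrom.sizes, variants TSV, gene models GFF3, fragments BED4, TADs BED3,
#' scores TSV (wide ChromHMM), interactions ibed, category lists, truth TSV.
#'
#' @param data Dataset list (see [simulate_dataset()]).
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(data, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_chrom_sizes(data$assembly, p("genome.sizes"))
  write_variants(data$variants, p("variants.tsv"))
  write_gene_models_gff3(data$gm, p("genes.gff3"))
  write_fragments(data$fragments, p("fragments.bed"))
  write_bed(data$tads, p("tads.bed"))
  write_scores(data$annotation, p("scores.tsv"))
  write_interactions(data$interactions, p("interactions.ibed"))
  writeLines(data$categories$cosmic, p("cosmic_genes.txt"))
  writeLines(data$categories$drug_target, p("drug_target_genes.txt"))
  readr::write_tsv(data$truth, p("truth.tsv"))
  invisible(dir)
}

#' Load a dataset written by [write_dataset()]
#'
#' @param dir Directory holding the standard files.
#' @return Dataset list with the same shape as [simulate_dataset()] output
#'   (without `config`).
#' @export
load_dataset <- function(dir) {
  p <- function(f) file.path(dir, f)
  assembly <- read_chrom_sizes(p("genome.sizes"))
  list(
    assembly = assembly,
    variants = read_variants(p("variants.tsv"), assembly),
    gm = read_gene_models(p("genes.gff3")),
    fragments = read_fragments(p("fragments.bed"), assembly),
    tads = if (file.exists(p("tads.bed"))) read_tads(p("tads.bed"), assembly) else NULL,
    annotation = read_scores(p("scores.tsv")),
    interactions = read_interactions(p("interactions.ibed"), cell_line = "merged"),
    categories = list(
      cosmic = if (file.exists(p("cosmic_genes.txt"))) readLines(p("cosmic_genes.txt")) else character(),
      drug_target = if (file.exists(p("drug_target_genes.txt"))) readLines(p("drug_target_genes.txt")) else character()
    ),
    truth = if (file.exists(p("truth.tsv"))) {
      readr::read_tsv(p("truth.tsv"), show_col_types = FALSE)
    } else tibble(gene_id = character(), cancers = character())
  )
}

#' Run the full analysis pipeline on one dataset
#'
#' Executes, in order: multi-trait clustering permutation test; per-cancer
#' region extension and multi-cancer region construction with signal counts;
#' variant location classification; interaction filtering, distal
#' variant-to-gene assignment and the TAD-enrichment permutation test;
#' candidate gene and lncRNA calling; Fisher and region-matched permutation
#' enrichment of the cancer-census and drug-target categories. Deterministic
#' stages are seed-independent; only the three permutation stages consume the
#' seed. When `data$tads` is `NULL` the linking stage runs with
#' `within_tad = FALSE` everywhere (with a message) and no distal evidence is
#' emitted.
#'
#' @param data Dataset list ([simulate_dataset()] or [load_dataset()]).
#' @param params Parameter list ([pipeline_params()]).
#' @param outdir Optional output directory; when given, regions (BED +
#'   summary TSV), candidate tables (TSV), test results (JSON) and a run
#'   manifest (JSON with parameters, seed and input hashes) are written.
#' @param run_cluster_test,run_tad_test Logical switches for the expensive
#'   permutation stages.
#' @return List with `cluster_test`, `per_cancer_regions`, `regions`,
#'   `location`, `interactions_hc`, `distal_links`, `tad_test`, `calls`,
#'   `lncrna_calls`, `enrichment` (per category: `fisher`, `matched`),
#'   `background`.
#' @export
run_pipeline <- function(data, params = pipeline_params(), outdir = NULL,
                         run_cluster_test = TRUE, run_tad_test = TRUE) {
  t0 <- Sys.time()
  asm <- data$assembly
  variants <- data$variants

  cluster_test <- NULL
  if (run_cluster_test) {
    cluster_test <- clustering_permutation_test(
      filter(variants, .data$is_index), asm,
      max_gap = params$max_gap, n_perms = params$n_perms_cluster,
      rng_seed = derive_seed(params$seed, 11L))
  }

  per_cancer <- build_cancer_regions(variants, asm, flank = params$flank)
  regions <- build_mhdcr_regions(per_cancer, asm,
                                 min_cancers = params$min_cancers)
  regions <- count_signals(regions, variants)

  location <- classify_location(variants, data$gm,
                                promoter_flank = params$promoter_flank)

  ints <- filter_interactions(data$interactions, min_score = params$min_score)
  links <- assign_distal(variants, data$fragments, ints, data$gm,
                         data$annotation, tads = data$tads,
                         location = location,
                         promoter_flank = params$promoter_flank)
  tad_test <- NULL
  if (run_tad_test && !is.null(data$tads) && nrow(regions)) {
    tad_test <- tad_enrichment(ints, data$tads, regions,
                               n_perms = params$n_perms_tad,
                               rng_seed = derive_seed(params$seed, 12L))
  }

  biosample_cancer <- data$annotation$biosample_cancer %||% NULL
  calls <- call_candidate_genes(
    regions, variants, data$annotation, links, data$gm,
    biotype = "protein_coding", location = location,
    promoter_flank = params$promoter_flank, min_cancers = params$min_cancers,
    biosample_cancer = biosample_cancer,
    cosmic_genes = data$categories$cosmic,
    drug_target_genes = data$categories$drug_target)
  lncrna_calls <- call_candidate_lncrnas(
    regions, variants, data$annotation, links, data$gm,
    location = location, promoter_flank = params$promoter_flank,
    min_cancers = params$min_cancers, biosample_cancer = biosample_cancer,
    cosmic_genes = data$categories$cosmic,
    drug_target_genes = data$categories$drug_target)

  # Background: all protein-coding genes overlapping any region.
  g <- data$gm$genes[data$gm$genes$biotype == "protein_coding", ]
  gene_region <- GenomicRanges::findOverlaps(
    iv_to_gr(tibble(chrom = g$chrom, start = g$start, end = g$end)),
    iv_to_gr(regions))
  background <- unique(g$gene_id[S4Vectors::queryHits(gene_region)])
  region_pools <- split(
    g$gene_id[S4Vectors::queryHits(gene_region)],
    as.character(regions$region_id[S4Vectors::subjectHits(gene_region)]))

  enrichment <- list()
  cand_ids <- calls$candidates$gene_id
  if (length(cand_ids) && length(background)) {
    cand_region <- vapply(calls$candidates$region_ids, function(x)
      as.character(x[1]), character(1))
    for (cat_name in c("cosmic", "drug_target")) {
      members <- data$categories[[cat_name]]
      fisher <- fisher_enrichment(cand_ids, members, background)
      matched <- tryCatch(
        matched_permutation_z(cand_ids, cand_region, members, region_pools,
                              n_perms = params$n_perms_matched,
                              rng_seed = derive_seed(params$seed, 13L)),
        error = function(e) NULL)
      enrichment[[cat_name]] <- list(fisher = fisher, matched = matched)
    }
  }

  result <- list(cluster_test = cluster_test, per_cancer_regions = per_cancer,
                 regions = regions, location = location,
                 interactions_hc = ints, distal_links = links,
                 tad_test = tad_test, calls = calls,
                 lncrna_calls = lncrna_calls, enrichment = enrichment,
                 background = background)

  if (!is.null(outdir)) {
    write_pipeline_outputs(result, data, params, outdir, t0)
  }
  result
}

perm_test_json <- function(x) {
  if (is.null(x)) return(NULL)
  list(observed = x$observed, z = x$z, z_defined = x$z_defined,
       p_empirical = x$p_empirical, p_is_upper_bound = x$p_is_upper_bound,
       n_perms = x$n_perms, seed = x$seed,
       null_mean = mean(x$null_values), null_sd = stats::sd(x$null_values))
}

candidates_tsv <- function(calls) {
  tibble(
    gene_id = calls$candidates$gene_id,
    name = calls$candidates$name,
    biotype = calls$candidates$biotype,
    regions = vapply(calls$candidates$region_ids, paste, character(1),
                     collapse = ","),
    cancers = vapply(calls$candidates$cancers, paste, character(1),
                     collapse = ","),
    evidence = calls$candidates$evidence,
    chromhmm_support = calls$candidates$chromhmm_support,
    cosmic = calls$candidates$cosmic,
    drug_target = calls$candidates$drug_target
  )
}

write_pipeline_outputs <- function(result, data, params, outdir, t0) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(outdir, f)
  write_regions(result$regions, p("regions.bed"), p("regions_summary.tsv"))
  readr::write_tsv(candidates_tsv(result$calls), p("candidates.tsv"))
  readr::write_tsv(candidates_tsv(result$lncrna_calls),
                   p("lncrna_candidates.tsv"))
  readr::write_tsv(result$calls$audit, p("evidence_audit.tsv"))
  links_out <- result$distal_links
  if (nrow(links_out)) {
    links_out$cell_lines <- vapply(links_out$cell_lines, paste, character(1),
                                   collapse = ",")
  } else {
    links_out$cell_lines <- character(0)
  }
  readr::write_tsv(links_out, p("distal_links.tsv"))
  tests <- list(cluster_test = perm_test_json(result$cluster_test),
                tad_test = perm_test_json(result$tad_test))
  jsonlite::write_json(tests, p("permutation_tests.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  enr <- lapply(result$enrichment, function(e) {
    list(table = as.vector(e$fisher$table),
         odds_ratio = e$fisher$odds_ratio,
         odds_ratio_mle = e$fisher$odds_ratio_mle,
         p_fisher = e$fisher$p_fisher,
         matched = perm_test_json(e$matched))
  })
  jsonlite::write_json(enr, p("enrichment.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  manifest <- list(
    pipeline = "pleiogene::run_pipeline",
    params = params,
    seed = params$seed,
    started = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    n_variants = nrow(data$variants),
    n_regions = nrow(result$regions),
    outputs = list.files(outdir)
  )
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(outdir)
}

#' Score recovery of planted truth genes
#'
#' Precision and recall of a candidate call against the generator's planted
#' truth table.
#'
#' @param calls A `candidate_calls` list.
#' @param truth Truth tibble with `gene_id`.
#' @return List `recall`, `precision`, `n_called`, `n_truth`,
#'   `true_positives`.
#' @export
score_recovery <- function(calls, truth) {
  called <- calls$candidates$gene_id
  tp <- intersect(called, truth$gene_id)
  list(
    recall = if (nrow(truth)) length(tp) / nrow(truth) else NA_real_,
    precision = if (length(called)) length(tp) / length(called) else NA_real_,
    n_called = length(called), n_truth = nrow(truth),
    true_positives = sort(tp)
  )
}
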