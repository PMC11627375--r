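#' Call candidate multi-cancer genes
#'
#' Integrates every evidence channel into per-gene, per-cancer categories and
#' emits genes supported by at least `min_cancers` distinct cancers:
#'
#' * coding — variant exonic for the gene with a retained VEP consequence
#'   (frameshift, missense, synonymous, utr5, utr3); for lncRNAs the exonic
#'   location alone gives category `exon`;
#' * `promoter` — variant in the gene's promoter (TSS +/- 2 kb);
#' * `splicing` — intronic variant passing [is_splice_altering()]
#'   (protein-coding mode only);
#' * `intronic_regulatory` — intronic variant passing [is_regulatory()];
#' * `distal_reg_within_tad` — distal link from [assign_distal()] with
#'   `within_tad = TRUE`.
#'
#' Variants outside every region are ignored; candidate genes are assigned to
#' every region they overlap (genes overlapping none are dropped with a
#' message). A gene counts toward a cancer through any single qualifying
#' variant. The full evidence trail (gene, cancer, category, variant) is
#' returned alongside the candidate table.
#'
#' @param regions Region tibble ([build_mhdcr_regions()]).
#' @param variants Variant tibble (candidate set: index variants and LD
#'   proxies).
#' @param annotation `annotation_scores` list ([read_scores()]).
#' @param distal_links Output of [assign_distal()] (may have zero rows).
#' @param gm A [gene_models()] object.
#' @param biotype Gene biotype to call (`"protein_coding"` or `"lncRNA"`).
#' @param channels Evidence channels to use; the default is all of
#'   `coding`, `promoter`, `splicing`, `intronic_regulatory`, `distal`.
#'   Restricting to `c("coding", "promoter", "splicing")` reproduces the
#'   coding-only first-pass call.
#' @param location Optional precomputed [classify_location()] table.
#' @param promoter_flank Promoter half-width in bp (default 2000).
#' @param min_cancers Minimum distinct cancers with evidence (default 2).
#' @param biosample_cancer Optional named character vector mapping biosample
#'   label to cancer; when given, ChromHMM support only counts biosamples of
#'   the gene's evidence cancers.
#' @param cosmic_genes,drug_target_genes Optional character vectors of gene
#'   ids used to set the `cosmic` / `drug_target` flags.
#' @return List of class `candidate_calls`: `candidates` (tibble `gene_id`,
#'   `name`, `biotype`, `region_ids` list-column, `cancers` list-column,
#'   `evidence` string summary, `chromhmm_support`, `cosmic`, `drug_target`)
#'   and `audit` (tibble `gene_id`, `cancer`, `category`, `variant_id`).
#' @export
call_candidate_genes <- function(regions, variants, annotation, distal_links,
                                 gm, biotype = "protein_coding",
                                 channels = c("coding", "promoter", "splicing",
                                              "intronic_regulatory", "distal"),
                                 location = NULL, promoter_flank = 2000,
                                 min_cancers = 2, biosample_cancer = NULL,
                                 cosmic_genes = NULL,
                                 drug_target_genes = NULL) {
  channels <- match.arg(channels, several.ok = TRUE)
  empty_audit <- tibble(gene_id = character(), cancer = character(),
                        category = character(), variant_id = character())
  empty <- structure(
    list(candidates = tibble(gene_id = character(), name = character(),
                             biotype = character(), region_ids = list(),
                             cancers = list(), evidence = character(),
                             chromhmm_support = logical(), cosmic = logical(),
                             drug_target = logical()),
         audit = empty_audit),
    class = "candidate_calls")

  # Keep only variants falling inside a multi-cancer region.
  if (nrow(regions)) {
    hit <- GenomicRanges::findOverlaps(
      iv_to_gr(tibble(chrom = variants$chrom, start = variants$pos,
                      end = variants$pos + 1)),
      iv_to_gr(regions), select = "first")
    variants <- variants[!is.na(hit), , drop = FALSE]
  } else {
    return(empty)
  }
  if (nrow(variants) == 0L) return(empty)

  location <- location %||% classify_location(variants, gm, promoter_flank)
  target_genes <- gm$genes$gene_id[gm$genes$biotype == biotype]
  loc <- filter(location, .data$gene_id %in% target_genes)
  scores <- annotation$scores
  vinfo <- distinct(variants[, c("variant_id", "cancer")])

  ev <- list()
  add <- function(df) if (nrow(df)) ev[[length(ev) + 1]] <<- df

  loc_cancer <- inner_join(loc, vinfo, by = "variant_id",
                           relationship = "many-to-many") |>
    left_join(scores, by = "variant_id")

  if ("coding" %in% channels) {
    exonic <- filter(loc_cancer, .data$location_class == "exonic")
    if (biotype == "protein_coding") {
      exonic <- mutate(exonic, category = coding_evidence(.data$vep_class)) |>
        filter(!is.na(.data$category))
    } else {
      exonic <- mutate(exonic, category = "exon")
    }
    add(select(exonic, "gene_id", "cancer", "category", "variant_id"))
  }
  if ("promoter" %in% channels) {
    add(loc_cancer |>
          filter(.data$location_class == "promoter") |>
          mutate(category = "promoter") |>
          select("gene_id", "cancer", "category", "variant_id"))
  }
  if ("splicing" %in% channels && biotype == "protein_coding") {
    add(loc_cancer |>
          filter(.data$location_class == "intronic",
                 is_splice_altering(.data$spliceai_delta, .data$maxentscan)) |>
          mutate(category = "splicing") |>
          select("gene_id", "cancer", "category", "variant_id"))
  }
  if ("intronic_regulatory" %in% channels) {
    add(loc_cancer |>
          filter(.data$location_class == "intronic",
                 is_regulatory(.data$regulome_probability)) |>
          mutate(category = "intronic_regulatory") |>
          select("gene_id", "cancer", "category", "variant_id"))
  }
  if ("distal" %in% channels && !is.null(distal_links) &&
      nrow(distal_links)) {
    missing_genes <- setdiff(distal_links$gene_id, gm$genes$gene_id)
    if (length(missing_genes)) {
      abort(paste0("Distal link references gene(s) absent from the gene",
                   " models: ", paste(missing_genes, collapse = ", ")))
    }
    add(distal_links |>
          filter(.data$within_tad, .data$gene_id %in% target_genes) |>
          inner_join(vinfo, by = "variant_id",
                     relationship = "many-to-many") |>
          mutate(category = "distal_reg_within_tad") |>
          select("gene_id", "cancer", "category", "variant_id"))
  }

  if (length(ev) == 0L) return(empty)
  audit <- distinct(bind_rows(ev))

  called <- audit |>
    group_by(.data$gene_id) |>
    summarise(n_cancers = dplyr::n_distinct(.data$cancer), .groups = "drop") |>
    filter(.data$n_cancers >= min_cancers)
  if (nrow(called) == 0L) return(empty)
  audit <- filter(audit, .data$gene_id %in% called$gene_id) |>
    arrange(.data$gene_id, .data$cancer, .data$category, .data$variant_id)

  g <- gm$genes[match(called$gene_id, gm$genes$gene_id), ]
  region_hits <- GenomicRanges::findOverlaps(
    iv_to_gr(tibble(chrom = g$chrom, start = g$start, end = g$end)),
    iv_to_gr(regions))
  region_ids <- lapply(seq_len(nrow(g)), function(i) {
    regions$region_id[S4Vectors::subjectHits(region_hits)[
      S4Vectors::queryHits(region_hits) == i]]
  })
  no_region <- lengths(region_ids) == 0L
  if (any(no_region)) {
    inform(paste0("Dropped ", sum(no_region),
                  " candidate gene(s) overlapping no region: ",
                  paste(g$gene_id[no_region], collapse = ", ")))
    g <- g[!no_region, , drop = FALSE]
    region_ids <- region_ids[!no_region]
    audit <- filter(audit, .data$gene_id %in% g$gene_id)
    if (nrow(g) == 0L) return(empty)
  }

  per_gene <- audit |>
    group_by(.data$gene_id) |>
    summarise(
      cancers = list(sort(unique(.data$cancer))),
      evidence = paste(sort(unique(paste0(.data$cancer, ":", .data$category))),
                       collapse = ";"),
      .groups = "drop")
  per_gene <- per_gene[match(g$gene_id, per_gene$gene_id), ]

  chromhmm_flag <- vapply(seq_len(nrow(g)), function(i) {
    vids <- unique(audit$variant_id[audit$gene_id == g$gene_id[i]])
    relevant <- NULL
    if (!is.null(biosample_cancer)) {
      relevant <- names(biosample_cancer)[
        biosample_cancer %in% per_gene$cancers[[i]]]
    }
    any(chromhmm_support(annotation$chromhmm, vids,
                         relevant_biosamples = relevant))
  }, logical(1))

  candidates <- tibble(
    gene_id = g$gene_id,
    name = g$name,
    biotype = g$biotype,
    region_ids = region_ids,
    cancers = per_gene$cancers,
    evidence = per_gene$evidence,
    chromhmm_support = chromhmm_flag,
    cosmic = g$gene_id %in% (cosmic_genes %||% character()),
    drug_target = g$gene_id %in% (drug_target_genes %||% character())
  ) |> arrange(.data$gene_id)

  structure(list(candidates = candidates, audit = audit),
            class = "candidate_calls")
}

#' @export
print.candidate_calls <- function(x, ...) {
  cat("candidate_calls: ", nrow(x$candidates), " genes, ",
      nrow(x$audit), " evidence rows\n", sep = "")
  invisible(x)
}

#' Call candidate multi-cancer lncRNAs
#'
#' Identical rules to [call_candidate_genes()] with `biotype = "lncRNA"` and
#' the lncRNA category set (`exon`, `promoter`, `intronic_regulatory`,
#' `distal_reg_within_tad`; no splicing channel).
#'
#' @inheritParams call_candidate_genes
#' @return A `candidate_calls` list.
#' @export
call_candidate_lncrnas <- function(regions, variants, annotation,
                                   distal_links, gm, location = NULL,
                                   promoter_flank = 2000, min_cancers = 2,
                                   biosample_cancer = NULL,
                                   cosmic_genes = NULL,
                                   drug_target_genes = NULL) {
  call_candidate_genes(regions, variants, annotation, distal_links, gm,
                       biotype = "lncRNA",
                       channels = c("coding", "promoter",
                                    "intronic_regulatory", "distal"),
                       location = location, promoter_flank = promoter_flank,
                       min_cancers = min_cancers,
                       biosample_cancer = biosample_cancer,
                       cosmic_genes = cosmic_genes,
                       drug_target_genes = drug_target_genes)
}

#' Fisher's exact enrichment of a gene category among candidates
#'
#' Builds the 2x2 table (candidate vs rest) x (in category vs not) over a
#' background gene set and tests one-sided (greater) enrichment. The reported
#' odds ratio is the sample OR `(a d) / (b c)`; when any cell is zero the
#' Haldane-Anscombe continuity correction (+0.5 to every cell) is applied and
#' flagged. The conditional-MLE OR from `fisher.test()` is also returned.
#'
#' @param candidates Character vector of candidate gene ids (must be a subset
#'   of `background`).
#' @param category_members Character vector of gene ids in the category.
#' @param background Character vector of all genes at the regions.
#' @return List of class `enrichment_result`: `table` (2x2 matrix),
#'   `odds_ratio`, `or_continuity`, `odds_ratio_mle`, `p_fisher`,
#'   `or_defined`.
#' @export
fisher_enrichment <- function(candidates, category_members, background) {
  background <- unique(background)
  if (length(background) == 0L) abort("`background` must be non-empty.")
  candidates <- unique(candidates)
  if (!all(candidates %in% background)) {
    abort("`candidates` must be a subset of `background`.")
  }
  rest <- setdiff(background, candidates)
  a <- sum(candidates %in% category_members)
  b <- length(candidates) - a
  cc <- sum(rest %in% category_members)
  d <- length(rest) - cc
  tab <- matrix(c(a, b, cc, d), nrow = 2, byrow = TRUE,
                dimnames = list(c("candidate", "rest"),
                                c("in_category", "not_in_category")))
  ft <- stats::fisher.test(tab, alternative = "greater")
  zero_cell <- any(tab == 0)
  if (a == 0 && cc == 0) {
    or <- NA_real_
    or_defined <- FALSE
  } else if (zero_cell) {
    or <- ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (cc + 0.5))
    or_defined <- TRUE
  } else {
    or <- (a * d) / (b * cc)
    or_defined <- TRUE
  }
  structure(
    list(table = tab, odds_ratio = or, or_continuity = zero_cell && or_defined,
         odds_ratio_mle = unname(ft$estimate), p_fisher = ft$p.value,
         or_defined = or_defined),
    class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  print(x$table)
  cat("sample OR: ", if (x$or_defined) signif(x$odds_ratio, 4) else "undefined",
      if (isTRUE(x$or_continuity)) " (continuity-corrected)" else "",
      "; Fisher p (greater): ", signif(x$p_fisher, 4), "\n", sep = "")
  invisible(x)
}

#' Region-matched permutation z-score for category enrichment
#'
#' Compares the observed number of candidates in a category to random gene
#' sets matched to the number of candidates per region: each iteration draws,
#' from every region's gene pool, as many genes (without replacement) as that
#' region contributed candidates, and counts draws in the category. The null
#' distribution is z-scaled. A `label-permutation` mode is also provided: the
#' category labels are permuted over the union of region gene pools and the
#' candidate overlap recounted.
#'
#' @param candidates Character vector of candidate gene ids.
#' @param candidate_regions Region id per candidate (same length; a candidate
#'   spanning several regions is attributed to one, conventionally its first).
#' @param category_members Character vector of category gene ids.
#' @param region_pools Named list: region id -> character vector of gene ids
#'   eligible in that region.
#' @param n_perms Number of iterations (default 10000).
#' @param rng_seed Integer seed.
#' @param null `"matched-sets"` (default) or `"label-permutation"`.
#' @return A [perm_test_result()] whose statistic is the category count.
#' @export
matched_permutation_z <- function(candidates, candidate_regions,
                                  category_members, region_pools,
                                  n_perms = 10000, rng_seed = NULL,
                                  null = c("matched-sets",
                                           "label-permutation")) {
  null <- match.arg(null)
  stopifnot(length(candidates) == length(candidate_regions))
  observed <- sum(candidates %in% category_members)
  if (null == "matched-sets") {
    k_by_region <- table(as.character(candidate_regions))
    pools <- lapply(names(k_by_region), function(r) {
      pool <- region_pools[[r]]
      if (is.null(pool) || length(pool) < k_by_region[[r]]) {
        abort(paste0("Region ", r, " has a gene pool smaller than its ",
                     k_by_region[[r]], " candidate(s)."))
      }
      list(in_cat = pool %in% category_members, k = k_by_region[[r]])
    })
    null_values <- with_seed(rng_seed, {
      vapply(seq_len(n_perms), function(i) {
        sum(vapply(pools, function(p) {
          sum(p$in_cat[sample.int(length(p$in_cat), p$k)])
        }, numeric(1)))
      }, numeric(1))
    })
  } else {
    all_genes <- unique(unlist(region_pools, use.names = FALSE))
    n_cat <- sum(all_genes %in% category_members)
    is_cand <- all_genes %in% candidates
    null_values <- with_seed(rng_seed, {
      vapply(seq_len(n_perms), function(i) {
        sum(is_cand[sample.int(length(all_genes), n_cat)])
      }, numeric(1))
    })
  }
  perm_test_result(observed, null_values, seed = rng_seed %||% NA_integer_)
}

#' Read a gene category list
#'
#' Either one gene id per line (no header) or a TSV with `gene_id` plus an
#' optional logical `member` column.
#'
#' @param path Path to the list.
#' @return Character vector of member gene ids.
#' @export
read_gene_category <- function(path) {
  first <- readLines(path, n = 1)
  if (grepl("\t", first) || grepl("^gene_id", first)) {
    df <- utils::read.table(path, sep = "\t", header = TRUE,
                            colClasses = "character")
    if ("member" %in% names(df)) {
      return(df$gene_id[toupper(df$member) %in% c("TRUE", "T", "1", "YES")])
    }
    return(df$gene_id)
  }
  readLines(path)
}
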