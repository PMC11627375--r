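#' Simulation configuration
#'
#' Bundles all parameters of the synthetic-data generator. Defaults mirror
#' the study conditions of the real analysis where those are known (variant
#' counts per cancer, 50 kb co-location window, ~4 kb HindIII-scale
#' fragments) and field-typical values elsewhere (200 kb mean TAD length,
#' geometric interaction distance decay).
#'
#' @param n_chromosomes Number of equal-length chromosomes (default 8).
#' @param chrom_length Chromosome length in bp (default 5e7).
#' @param variants_per_cancer Named integer vector of index-variant counts
#'   (default `c(breast = 196, endometrial = 17, ovarian = 60,
#'   prostate = 258)`, the real index-set sizes).
#' @param pleiotropy_fraction Fraction of non-breast variants placed within
#'   `co_locate_window` of a random breast variant (default 0.5).
#' @param co_locate_window Co-location window in bp (default 50 kb).
#' @param n_genes Number of genes (default 400).
#' @param lncrna_fraction Fraction of genes simulated as lncRNA (default 0.2).
#' @param fragment_mean_length Mean restriction fragment length in bp
#'   (default 4 kb).
#' @param tad_mean_length Mean TAD length in bp (default 200 kb).
#' @param tad_gap_mean Mean inter-TAD boundary gap in bp (default 800 kb);
#'   TADs are sparse domains, not a gapless tiling, as in real TAD maps.
#' @param interaction_count Number of interactions to draw (default 1000).
#' @param within_tad_enrichment Relative propensity (>= 1) of interactions
#'   whose anchors share a TAD (default 3).
#' @param interaction_decay_fragments Mean bait/other-end offset in fragments
#'   of the geometric distance decay (default 25).
#' @param regulatory_fraction Fraction of noncoding variants given a
#'   RegulomeDB probability above 0.55 (default 0.3).
#' @param n_true_genes Number of planted pleiotropic genes; 0 disables
#'   planted-truth mode (default 0).
#' @param seed Integer master seed (default 1).
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_chromosomes = 8,
                       chrom_length = 5e7,
                       variants_per_cancer = c(breast = 196, endometrial = 17,
                                               ovarian = 60, prostate = 258),
                       pleiotropy_fraction = 0.5,
                       co_locate_window = 50000,
                       n_genes = 400,
                       lncrna_fraction = 0.2,
                       fragment_mean_length = 4000,
                       tad_mean_length = 200000,
                       tad_gap_mean = 800000,
                       interaction_count = 1000,
                       within_tad_enrichment = 3,
                       interaction_decay_fragments = 25,
                       regulatory_fraction = 0.3,
                       n_true_genes = 0,
                       seed = 1) {
  cfg <- list(n_chromosomes = n_chromosomes, chrom_length = chrom_length,
              variants_per_cancer = variants_per_cancer,
              pleiotropy_fraction = pleiotropy_fraction,
              co_locate_window = co_locate_window,
              n_genes = n_genes, lncrna_fraction = lncrna_fraction,
              fragment_mean_length = fragment_mean_length,
              tad_mean_length = tad_mean_length,
              tad_gap_mean = tad_gap_mean,
              interaction_count = interaction_count,
              within_tad_enrichment = within_tad_enrichment,
              interaction_decay_fragments = interaction_decay_fragments,
              regulatory_fraction = regulatory_fraction,
              n_true_genes = n_true_genes,
              seed = seed)
  stopifnot(
    is_count(n_chromosomes) && n_chromosomes >= 1,
    chrom_length > 0,
    !is.null(names(variants_per_cancer)),
    "breast" %in% names(variants_per_cancer),
    all(variants_per_cancer >= 0),
    pleiotropy_fraction >= 0 && pleiotropy_fraction <= 1,
    lncrna_fraction >= 0 && lncrna_fraction <= 1,
    regulatory_fraction >= 0 && regulatory_fraction <= 1,
    co_locate_window > 0, fragment_mean_length > 0, tad_mean_length > 0,
    tad_gap_mean > 0,
    within_tad_enrichment >= 1,
    is_count(n_true_genes)
  )
  class(cfg) <- "sim_config"
  cfg
}

#' Assembly implied by a simulation configuration
#' @param config A [sim_config()].
#' @return A [genome_assembly()] with chromosomes `chr1..chrN`.
#' @export
sim_assembly <- function(config) {
  genome_assembly(paste0("chr", seq_len(config$n_chromosomes)),
                  rep(config$chrom_length, config$n_chromosomes),
                  name = "synthetic")
}

# Derive a stage-specific seed from the master seed (kept < 2^31).
derive_seed <- function(seed, stage) {
  (abs(seed) * 131L + stage) %% 2147483647L
}

#' Simulate GWAS index variants with tunable cross-cancer co-location
#'
#' Breast variants are placed uniformly. Each other cancer's variant is, with
#' probability `pleiotropy_fraction`, placed within `co_locate_window` of a
#' random breast variant (the planted pleiotropy signal), otherwise
#' uniformly. Signal ids are unique per variant; every variant is an index
#' variant.
#'
#' @param config A [sim_config()].
#' @param seed Seed (default derived from `config$seed`).
#' @return Variant tibble.
#' @export
simulate_variants <- function(config, seed = derive_seed(config$seed, 1L)) {
  asm <- sim_assembly(config)
  with_seed(seed, {
    counts <- config$variants_per_cancer
    n_b <- counts[["breast"]]
    b_chrom <- sample(asm$chrom, n_b, replace = TRUE)
    b_pos <- runif_pos(n_b, chrom_length(asm, b_chrom))
    out <- list(tibble(chrom = b_chrom, pos = b_pos, cancer = "breast"))
    for (cc in setdiff(names(counts), "breast")) {
      n <- counts[[cc]]
      if (n == 0) next
      co <- stats::runif(n) < config$pleiotropy_fraction
      chrom <- character(n)
      pos <- numeric(n)
      if (any(co)) {
        anchor <- sample.int(n_b, sum(co), replace = TRUE)
        chrom[co] <- b_chrom[anchor]
        off <- round(stats::runif(sum(co), -config$co_locate_window,
                                  config$co_locate_window))
        pos[co] <- pmin(pmax(b_pos[anchor] + off, 0),
                        chrom_length(asm, chrom[co]) - 1)
      }
      if (any(!co)) {
        chrom[!co] <- sample(asm$chrom, sum(!co), replace = TRUE)
        pos[!co] <- runif_pos(sum(!co), chrom_length(asm, chrom[!co]))
      }
      out[[length(out) + 1]] <- tibble(chrom = chrom, pos = pos, cancer = cc)
    }
    v <- bind_rows(out)
    mutate(v,
           variant_id = paste0("rs_sim", sprintf("%05d", row_number())),
           signal_id = paste0("sig_", .data$cancer, "_",
                              sprintf("%04d", row_number())),
           is_index = TRUE, r2 = 1) |>
      select("variant_id", "chrom", "pos", "cancer", "signal_id",
             "is_index", "r2")
  })
}

# Tile [0, len) with ~exponential segment lengths of the given mean.
tile_chromosome <- function(len, mean_length, min_length = 1) {
  n_guess <- ceiling(len / mean_length * 1.5) + 10
  lens <- pmax(min_length, ceiling(stats::rexp(n_guess, 1 / mean_length)))
  while (sum(lens) < len) {
    lens <- c(lens, pmax(min_length, ceiling(stats::rexp(n_guess, 1 / mean_length))))
  }
  ends <- pmin(cumsum(lens), len)
  ends <- ends[ends <= len]
  ends <- unique(c(ends[ends < len], len))
  tibble(start = c(0, ends[-length(ends)]), end = ends)
}

#' Simulate gene models, a restriction fragment map and a TAD tiling
#'
#' Genes get 2-10 exons with short exons and longer introns, random strand
#' (TSS consistent with strand), and are placed without overlap (>= 10 kb
#' apart so promoters never touch a neighbouring gene). Fragments and TADs
#' tile every chromosome exactly (no gaps, no overlaps) with exponential-ish
#' lengths of the configured means.
#'
#' @param config A [sim_config()].
#' @param seed Seed (default derived from `config$seed`).
#' @return List with `gm` ([gene_models()]), `fragments`, `tads`.
#' @export
simulate_genome_annotation <- function(config,
                                       seed = derive_seed(config$seed, 2L)) {
  asm <- sim_assembly(config)
  with_seed(seed, {
    fragments <- bind_rows(lapply(asm$chrom, function(ch) {
      mutate(tile_chromosome(chrom_length(asm, ch),
                             config$fragment_mean_length, min_length = 200),
             chrom = ch)
    }))
    fragments <- tibble(fragment_id = paste0("frag", seq_len(nrow(fragments))),
                        chrom = fragments$chrom, start = fragments$start,
                        end = fragments$end)
    # TADs: alternating boundary gap / domain segments (sparse, disjoint).
    tads <- bind_rows(lapply(asm$chrom, function(ch) {
      len <- chrom_length(asm, ch)
      segs <- tile_chromosome(len, (config$tad_mean_length +
                                      config$tad_gap_mean) / 2,
                              min_length = 20000)
      # Odd segments are gaps, even segments are TADs; rescale segment
      # lengths so domains and gaps get their configured means on average.
      is_tad <- seq_len(nrow(segs)) %% 2 == 0
      mean_seg <- (config$tad_mean_length + config$tad_gap_mean) / 2
      scale <- ifelse(is_tad, config$tad_mean_length / mean_seg,
                      config$tad_gap_mean / mean_seg)
      lens <- pmax(20000, round((segs$end - segs$start) * scale))
      ends <- pmin(cumsum(lens), len)
      starts <- c(0, ends[-length(ends)])
      ok <- is_tad & starts < ends
      tibble(chrom = ch, start = starts[ok], end = ends[ok])
    }))[, c("chrom", "start", "end")]

    # Non-overlapping gene placement with a 10 kb pad.
    genes <- list(); exons <- list()
    occupied <- lapply(asm$chrom, function(ch) matrix(numeric(0), ncol = 2))
    names(occupied) <- asm$chrom
    i <- 0L; tries <- 0L
    while (i < config$n_genes && tries < config$n_genes * 200L) {
      tries <- tries + 1L
      ch <- sample(asm$chrom, 1)
      n_ex <- sample(2:10, 1)
      ex_len <- round(stats::runif(n_ex, 100, 1500))
      in_len <- round(stats::runif(n_ex - 1, 500, 20000))
      span <- sum(ex_len) + sum(in_len)
      # 3 kb pad at chromosome ends so promoters never clip.
      start <- 3000 + runif_pos(1, chrom_length(asm, ch) - span - 6000)
      occ <- occupied[[ch]]
      if (nrow(occ) &&
          any(start < occ[, 2] + 10000 & start + span > occ[, 1] - 10000)) {
        next
      }
      i <- i + 1L
      occupied[[ch]] <- rbind(occ, c(start, start + span))
      gid <- paste0("G", sprintf("%04d", i))
      ex_start <- start + cumsum(c(0, ex_len[-n_ex] + in_len))
      genes[[i]] <- tibble(
        gene_id = gid, name = paste0("GENE", sprintf("%04d", i)),
        biotype = if (stats::runif(1) < config$lncrna_fraction) "lncRNA" else "protein_coding",
        chrom = ch, strand = sample(c("+", "-"), 1))
      exons[[i]] <- tibble(gene_id = gid, chrom = ch, start = ex_start,
                           end = ex_start + ex_len)
    }
    if (i < config$n_genes) {
      abort("Could not place all genes without overlap; lower `n_genes`.")
    }
    list(gm = gene_models(bind_rows(genes), bind_rows(exons)),
         fragments = fragments, tads = tads)
  })
}

#' Simulate per-variant functional scores and ChromHMM states
#'
#' Regulome probabilities follow a two-component mixture so that, among
#' noncoding variants, a `regulatory_fraction` share exceeds the 0.55
#' threshold. Exonic variants receive sparse VEP consequences; SpliceAI /
#' MaxEntScan values are mostly missing with occasional qualifying values
#' among intronic variants. ChromHMM states cover 12 biosamples (3 breast,
#' 1 endometrial, 3 ovarian, 5 prostate): regulatory variants tend to get an
#' active state in their own cancer's biosamples. Variants named in
#' `planted_ids` always qualify as regulatory and active (the planted truth
#' must be recoverable by design, not by luck).
#'
#' @param variants Variant tibble.
#' @param gm A [gene_models()] object.
#' @param config A [sim_config()].
#' @param planted_ids Character vector of planted variant ids.
#' @param seed Seed (default derived from `config$seed`).
#' @return An `annotation_scores` list (see [read_scores()]).
#' @export
simulate_scores <- function(variants, gm, config, planted_ids = character(),
                            seed = derive_seed(config$seed, 3L)) {
  loc <- classify_location(variants, gm)
  summ <- summarize_location(variants, loc)
  with_seed(seed, {
    v <- distinct(variants[, c("variant_id", "cancer")], .data$variant_id,
                  .keep_all = TRUE) |>
      left_join(summ, by = "variant_id")
    n <- nrow(v)
    exonic <- v$location_summary == "exonic"
    intronic <- v$location_summary == "intronic"
    planted <- v$variant_id %in% planted_ids

    vep <- rep("none", n)
    vep[exonic] <- sample(c("missense", "synonymous", "utr5", "utr3",
                            "frameshift", "other"),
                          sum(exonic), replace = TRUE,
                          prob = c(0.25, 0.2, 0.1, 0.1, 0.05, 0.3))

    reg <- stats::runif(n) < config$regulatory_fraction
    reg[planted] <- TRUE
    prob <- ifelse(reg, stats::runif(n, 0.551, 1), stats::runif(n, 0, 0.549))
    rank <- ifelse(prob > 0.9, "1a", ifelse(prob > 0.55, "2b", "5"))

    delta <- rep(NA_real_, n)
    has_delta <- intronic & stats::runif(n) < 0.15
    qualifying <- has_delta & stats::runif(n) < 1 / 3
    delta[has_delta & !qualifying] <- stats::runif(sum(has_delta & !qualifying), 0, 0.19)
    delta[qualifying] <- stats::runif(sum(qualifying), 0.2, 1)
    maxent <- rep(NA_real_, n)
    has_me <- intronic & stats::runif(n) < 0.03
    me_val <- stats::runif(sum(has_me), 0.5, 8) * sample(c(-1, 1), sum(has_me),
                                                         replace = TRUE)
    maxent[has_me] <- me_val

    scores <- tibble(variant_id = v$variant_id, vep_class = vep,
                     spliceai_delta = delta, maxentscan = maxent,
                     regulome_rank = rank, regulome_probability = prob)

    biosamples <- c(paste0("breast_", 1:3), "endometrial_1",
                    paste0("ovarian_", 1:3), paste0("prostate_", 1:5))
    bio_cancer <- sub("_[0-9]+$", "", biosamples)
    active <- active_chromhmm_states()
    chromhmm <- tidyr::expand_grid(variant_id = v$variant_id,
                                   biosample = biosamples) |>
      left_join(v[, c("variant_id", "cancer")], by = "variant_id") |>
      mutate(own = sub("_[0-9]+$", "", .data$biosample) == .data$cancer)
    is_reg <- reg[match(chromhmm$variant_id, v$variant_id)]
    is_planted <- planted[match(chromhmm$variant_id, v$variant_id)]
    p_active <- ifelse(is_planted & chromhmm$own, 1,
                       ifelse(is_reg & chromhmm$own, 0.8,
                              ifelse(is_reg, 0.2, 0.05)))
    draw_active <- stats::runif(nrow(chromhmm)) < p_active
    chromhmm$state <- ifelse(draw_active,
                             sample(active, nrow(chromhmm), replace = TRUE),
                             "Quies")
    chromhmm <- chromhmm[, c("variant_id", "biosample", "state")]
    structure(list(scores = scores, chromhmm = chromhmm,
                   biosample_cancer = stats::setNames(bio_cancer, biosamples)),
              class = "annotation_scores")
  })
}

#' Simulate promoter-capture interaction calls
#'
#' Baited fragments are exactly those overlapping a gene promoter. For each
#' interaction a bait is drawn uniformly and the other end at a geometric
#' fragment offset (distance decay); pairs whose fragment midpoints do not
#' share a TAD are thinned by `1 / within_tad_enrichment` (rejection
#' sampling), so `within_tad_enrichment = 1` gives no TAD structure. Scores
#' are drawn so that most interactions pass the confidence threshold of 5.
#'
#' @param fragments Fragment tibble.
#' @param gm A [gene_models()] object.
#' @param tads TAD tibble.
#' @param config A [sim_config()].
#' @param seed Seed (default derived from `config$seed`).
#' @return Interaction tibble (see [read_interactions()]).
#' @export
simulate_interactions <- function(fragments, gm, tads, config,
                                  seed = derive_seed(config$seed, 4L)) {
  prom <- promoter_intervals(gm)
  baited_idx <- unique(S4Vectors::queryHits(GenomicRanges::findOverlaps(
    iv_to_gr(fragments), iv_to_gr(prom))))
  if (length(baited_idx) == 0L) abort("No fragment overlaps a promoter.")
  frag_mid <- fragment_midpoint(fragments$start, fragments$end)
  frag_tad <- tad_of_point(fragments$chrom, frag_mid, tads)
  n_frag <- nrow(fragments)
  # Fragments are rows sorted per chromosome; an offset in rows stays on the
  # chromosome after the boundary check below.
  cell_lines <- paste0(rep(c("breast", "endometrial", "ovarian", "prostate"),
                           each = 3), "_line", 1:3)
  with_seed(seed, {
    acc <- list()
    n_acc <- 0L
    while (n_acc < config$interaction_count) {
      m <- (config$interaction_count - n_acc) * 3L + 50L
      bait <- sample(baited_idx, m, replace = TRUE)
      off <- (stats::rgeom(m, 1 / config$interaction_decay_fragments) + 1L) *
        sample(c(-1L, 1L), m, replace = TRUE)
      oe <- bait + off
      ok <- oe >= 1 & oe <= n_frag & fragments$chrom[pmax(1, pmin(n_frag, oe))] ==
        fragments$chrom[bait]
      bait <- bait[ok]; oe <- oe[ok]
      same_tad <- !is.na(frag_tad[bait]) & !is.na(frag_tad[oe]) &
        frag_tad[bait] == frag_tad[oe]
      keep <- same_tad | stats::runif(length(bait)) <
        1 / config$within_tad_enrichment
      bait <- bait[keep]; oe <- oe[keep]
      if (length(bait)) {
        acc[[length(acc) + 1]] <- tibble(bait = bait, oe = oe)
        n_acc <- n_acc + length(bait)
      }
    }
    pairs <- bind_rows(acc)[seq_len(config$interaction_count), ]
    score <- ifelse(stats::runif(nrow(pairs)) < 0.85,
                    stats::runif(nrow(pairs), 5, 20),
                    stats::runif(nrow(pairs), 0, 5))
    tibble(
      bait_chrom = fragments$chrom[pairs$bait],
      bait_start = fragments$start[pairs$bait],
      bait_end = fragments$end[pairs$bait],
      oe_chrom = fragments$chrom[pairs$oe],
      oe_start = fragments$start[pairs$oe],
      oe_end = fragments$end[pairs$oe],
      cell_line = sample(cell_lines, nrow(pairs), replace = TRUE),
      n_reads = stats::rpois(nrow(pairs), pmax(1, score) * 3) + 1,
      score = round(score, 2)
    )
  })
}

#' Simulate gene category membership (cancer-census and drug-target lists)
#'
#' Background genes are members at a low base rate; planted-truth genes at an
#' elevated rate, emulating the enrichment of curated cancer genes and drug
#' targets among real multi-cancer candidates.
#'
#' @param gm A [gene_models()] object.
#' @param truth_gene_ids Character vector of planted gene ids.
#' @param config A [sim_config()].
#' @param seed Seed (default derived from `config$seed`).
#' @return List `cosmic`, `drug_target` (character vectors of gene ids).
#' @export
simulate_gene_categories <- function(gm, truth_gene_ids = character(), config,
                                     seed = derive_seed(config$seed, 5L)) {
  with_seed(seed, {
    ids <- gm$genes$gene_id
    truth <- ids %in% truth_gene_ids
    cosmic <- stats::runif(length(ids)) < ifelse(truth, 0.3, 0.08)
    drug <- stats::runif(length(ids)) < ifelse(truth, 0.4, 0.15)
    list(cosmic = ids[cosmic], drug_target = ids[drug])
  })
}

#' Simulate a complete synthetic dataset
#'
#' Generates every pipeline input from one configuration and master seed:
#' assembly, gene models, fragment map, TADs, variants, functional scores,
#' interactions and gene category lists. When `n_true_genes > 0`, that many
#' protein-coding genes are designated as planted pleiotropic truth: for each,
#' two distinct cancers receive an index variant in the gene's promoter
#' (upstream of the first exon, so the promoter class is unambiguous), and a
#' truth table is returned for recovery scoring. Planted variants replace
#' background variants so per-cancer counts still match the configuration.
#'
#' @param config A [sim_config()].
#' @return List `config`, `assembly`, `gm`, `fragments`, `tads`, `variants`,
#'   `annotation`, `interactions`, `categories`, `truth` (tibble `gene_id`,
#'   `cancers`; zero rows when planting is off).
#' @export
simulate_dataset <- function(config = sim_config()) {
  asm <- sim_assembly(config)
  ann <- simulate_genome_annotation(config)
  variants <- simulate_variants(config)

  truth <- tibble(gene_id = character(), cancers = character())
  planted_ids <- character()
  if (config$n_true_genes > 0) {
    pc <- ann$gm$genes[ann$gm$genes$biotype == "protein_coding", ]
    if (nrow(pc) < config$n_true_genes) {
      abort("Fewer protein-coding genes than `n_true_genes`.")
    }
    planted <- with_seed(derive_seed(config$seed, 6L), {
      sel <- pc[sample.int(nrow(pc), config$n_true_genes), ]
      rows <- lapply(seq_len(nrow(sel)), function(i) {
        cancers <- sample(names(config$variants_per_cancer), 2)
        # Upstream of the first exon so the location class is promoter.
        offset <- round(stats::runif(2, 100, 1800))
        pos <- if (sel$strand[i] == "+") sel$tss[i] - offset else sel$tss[i] + offset
        tibble(gene_id = sel$gene_id[i], cancer = cancers, chrom = sel$chrom[i],
               pos = pos)
      })
      bind_rows(rows)
    })
    planted_v <- tibble(
      variant_id = paste0("rs_planted", sprintf("%03d", seq_len(nrow(planted)))),
      chrom = planted$chrom, pos = planted$pos, cancer = planted$cancer,
      signal_id = paste0("sig_planted_", seq_len(nrow(planted))),
      is_index = TRUE, r2 = 1)
    planted_ids <- planted_v$variant_id
    # Replace background variants so per-cancer totals are conserved.
    for (cc in unique(planted_v$cancer)) {
      k <- sum(planted_v$cancer == cc)
      drop_idx <- which(variants$cancer == cc)
      if (length(drop_idx) < k) {
        abort(paste0("Too few background variants for cancer ", cc,
                     " to plant the truth."))
      }
      variants <- variants[-drop_idx[seq_len(k)], ]
    }
    variants <- bind_rows(variants, planted_v)
    truth <- planted |>
      group_by(.data$gene_id) |>
      summarise(cancers = paste(sort(unique(.data$cancer)), collapse = ","),
                .groups = "drop")
  }

  annotation <- simulate_scores(variants, ann$gm, config,
                                planted_ids = planted_ids)
  interactions <- simulate_interactions(ann$fragments, ann$gm, ann$tads,
                                        config)
  categories <- simulate_gene_categories(ann$gm, truth$gene_id, config)
  list(config = config, assembly = asm, gm = ann$gm,
       fragments = ann$fragments, tads = ann$tads, variants = variants,
       annotation = annotation, interactions = interactions,
       categories = categories, truth = truth)
}

#' In-silico HindIII digest of a FASTA sequence set
#'
#' Cuts every sequence one base after the start of each `AAGCTT` recognition
#' site (the A^AGCTT cut) and returns the resulting fragment tiling in
#' 0-based half-open coordinates.
#'
#' @param path Path to a FASTA file.
#' @return Fragment tibble (`fragment_id`, `chrom`, `start`, `end`).
#' @export
digest_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  out <- lapply(seq_along(seqs), function(i) {
    hits <- Biostrings::matchPattern("AAGCTT", seqs[[i]])
    cuts <- BiocGenerics::start(hits)  # 1-based site start; cut after 1 base
    bounds <- sort(unique(c(0, cuts, length(seqs[[i]]))))
    tibble(chrom = names(seqs)[i],
           start = bounds[-length(bounds)], end = bounds[-1])
  })
  frags <- bind_rows(out)
  tibble(fragment_id = paste0("frag", seq_len(nrow(frags))),
         chrom = frags$chrom, start = frags$start, end = frags$end)
}
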