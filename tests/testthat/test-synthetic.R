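test_that("variant generation conserves counts and honours the co-location window", {
  cfg <- sim_config(seed = 41, n_chromosomes = 2, chrom_length = 5e6,
                    variants_per_cancer = c(breast = 50, endometrial = 10,
                                            ovarian = 20, prostate = 40))
  v <- simulate_variants(cfg)
  expect_equal(as.vector(table(v$cancer)[names(cfg$variants_per_cancer)]),
               unname(cfg$variants_per_cancer))
  expect_false(anyDuplicated(v$signal_id) > 0)

  # pleiotropy 1: every non-breast variant within the window of some breast
  cfg1 <- sim_config(seed = 42, n_chromosomes = 2, chrom_length = 5e6,
                     variants_per_cancer = c(breast = 50, endometrial = 10,
                                             ovarian = 20, prostate = 40),
                     pleiotropy_fraction = 1, co_locate_window = 50000)
  v1 <- simulate_variants(cfg1)
  b <- v1[v1$cancer == "breast", ]
  other <- v1[v1$cancer != "breast", ]
  near <- vapply(seq_len(nrow(other)), function(i) {
    any(b$chrom == other$chrom[i] & abs(b$pos - other$pos[i]) <= 50000)
  }, logical(1))
  expect_true(all(near))

  # determinism: same config and seed give identical output
  expect_identical(simulate_variants(cfg), simulate_variants(cfg))
})

test_that("fragments tile every chromosome exactly once and TADs are disjoint", {
  cfg <- sim_config(seed = 43, n_chromosomes = 2, chrom_length = 3e6,
                    n_genes = 50)
  ann <- simulate_genome_annotation(cfg)
  asm <- sim_assembly(cfg)
  for (ch in asm$chrom) {
    f <- ann$fragments[ann$fragments$chrom == ch, ]
    f <- f[order(f$start), ]
    expect_equal(f$start[1], 0)
    expect_equal(f$end[nrow(f)], 3e6)
    expect_true(all(f$start[-1] == f$end[-nrow(f)]))  # no gaps, no overlap
    tt <- ann$tads[ann$tads$chrom == ch, ]
    tt <- tt[order(tt$start), ]
    if (nrow(tt) > 1) expect_true(all(tt$start[-1] >= tt$end[-nrow(tt)]))
  }
  # TSS lies on the 5'-most exon boundary respecting strand
  g <- ann$gm$genes
  expect_true(all(g$tss[g$strand == "+"] == g$start[g$strand == "+"]))
  expect_true(all(g$tss[g$strand == "-"] == g$end[g$strand == "-"] - 1))
})

test_that("an in-silico HindIII digest cuts at every AAGCTT site", {
  withr::local_seed(444)
  seq1 <- paste(sample(c("A", "C", "G", "T"), 10000, replace = TRUE),
                collapse = "")
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">chrT", seq1), fa)
  frags <- digest_fasta(fa)
  # string-search oracle: cut one base after each site start
  sites <- gregexpr("AAGCTT", seq1)[[1]]
  cuts <- if (sites[1] == -1) numeric() else as.numeric(sites)
  bounds <- sort(unique(c(0, cuts, nchar(seq1))))
  expect_equal(frags$start, bounds[-length(bounds)])
  expect_equal(frags$end, bounds[-1])
})

test_that("score generation hits the configured regulatory fraction", {
  cfg <- sim_config(seed = 45, regulatory_fraction = 0.3)
  d_ann <- simulate_genome_annotation(cfg)
  v <- simulate_variants(cfg)
  ann <- simulate_scores(v, d_ann$gm, cfg)
  loc <- summarize_location(v, classify_location(v, d_ann$gm))
  noncoding <- loc$variant_id[loc$location_summary != "exonic"]
  frac <- mean(ann$scores$regulome_probability[
    ann$scores$variant_id %in% noncoding] > 0.55)
  expect_lt(abs(frac - 0.3), 0.05)
  expect_true(all(ann$scores$regulome_probability >= 0 &
                    ann$scores$regulome_probability <= 1))
  # determinism of the full score table
  ann2 <- simulate_scores(v, d_ann$gm, cfg)
  expect_identical(ann$scores, ann2$scores)
  expect_identical(ann$chromhmm, ann2$chromhmm)
})

test_that("every simulated interaction baits a promoter-overlapping fragment", {
  cfg <- sim_config(seed = 46, n_chromosomes = 2, chrom_length = 3e6,
                    n_genes = 50, interaction_count = 200)
  ann <- simulate_genome_annotation(cfg)
  ints <- simulate_interactions(ann$fragments, ann$gm, ann$tads, cfg)
  expect_equal(nrow(ints), 200)
  prom <- promoter_intervals(ann$gm)
  baited <- GenomicRanges::findOverlaps(
    pleiogene:::iv_to_gr(tibble::tibble(chrom = ints$bait_chrom,
                                        start = ints$bait_start,
                                        end = ints$bait_end)),
    pleiogene:::iv_to_gr(prom))
  expect_setequal(S4Vectors::queryHits(baited), seq_len(nrow(ints)))
  # bait and other end always differ and share a chromosome
  expect_true(all(ints$bait_start != ints$oe_start |
                    ints$bait_chrom != ints$oe_chrom))
  expect_true(all(ints$bait_chrom == ints$oe_chrom))
})

test_that("planted-truth datasets keep per-cancer counts and mark planted variants", {
  cfg <- sim_config(seed = 47, n_true_genes = 6, pleiotropy_fraction = 0)
  d <- simulate_dataset(cfg)
  expect_equal(nrow(d$truth), 6)
  expect_equal(as.vector(table(d$variants$cancer)[names(cfg$variants_per_cancer)]),
               unname(cfg$variants_per_cancer))
  # each planted gene has promoter variants from exactly two cancers
  planted <- d$variants[grepl("^rs_planted", d$variants$variant_id), ]
  expect_equal(nrow(planted), 12)
  loc <- classify_location(planted, d$gm)
  truth_rows <- loc[loc$gene_id %in% d$truth$gene_id, ]
  expect_true(all(truth_rows$location_class == "promoter"))
  # planted variants always qualify as regulatory
  sc <- d$annotation$scores
  expect_true(all(sc$regulome_probability[
    sc$variant_id %in% planted$variant_id] > 0.55))
})
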