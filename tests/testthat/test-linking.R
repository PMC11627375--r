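test_that("interaction score filtering keeps the boundary and is idempotent", {
  ints <- tibble::tibble(
    bait_chrom = "chr1", bait_start = c(0, 100, 200), bait_end = c(50, 150, 250),
    oe_chrom = "chr1", oe_start = c(500, 600, 700), oe_end = c(550, 650, 750),
    cell_line = "L1", n_reads = c(10, 20, 30), score = c(5.0, 4.99, 12))
  kept <- filter_interactions(ints)
  expect_equal(kept$score, c(5.0, 12))
  expect_equal(filter_interactions(kept), kept)
  expect_equal(nrow(filter_interactions(ints[0, ])), 0)
})

test_that("replicate concordance is a Spearman correlation over the key union", {
  mk <- function(starts, reads) tibble::tibble(
    bait_chrom = "chr1", bait_start = starts, bait_end = starts + 10,
    oe_chrom = "chr1", oe_start = starts + 1000, oe_end = starts + 1010,
    cell_line = "L", n_reads = reads, score = 6)
  r1 <- mk(1:10 * 100, 1:10)
  expect_equal(replicate_concordance(r1, r1)$rho, 1)
  r_rev <- mk(1:10 * 100, 10:1)
  expect_equal(replicate_concordance(r1, r_rev)$rho, -1)

  # random instance vs a naive rank-then-Pearson oracle
  withr::local_seed(111)
  x <- rpois(50, 20); y <- rpois(50, 20)
  ra <- mk(1:50 * 100, x); rb <- mk(1:50 * 100, y)
  expect_equal(replicate_concordance(ra, rb)$rho, oracle_spearman(x, y))

  # missing pairs contribute zero counts
  rc <- mk(1:4 * 100, c(5, 6, 7, 8))
  rd <- mk(2:5 * 100, c(6, 7, 8, 9))
  conc <- replicate_concordance(rc, rd)
  expect_equal(conc$n_pairs, 5)
  expect_true(conc$defined)
  # fewer than 3 shared keys -> undefined
  expect_false(replicate_concordance(mk(1:3 * 100, 1:3),
                                     mk(7:9 * 100, 1:3))$defined)
})

make_link_fixture <- function() {
  # fragments tile chr1 [0, 10000) in 1 kb steps; F3 holds the promoter of G,
  # F8 holds the variant; TAD covers [0, 9000)
  fragments <- tibble::tibble(
    fragment_id = paste0("F", 1:10), chrom = "chr1",
    start = 0:9 * 1000, end = 1:10 * 1000)
  genes <- tibble::tibble(gene_id = "G", name = "G", biotype = "protein_coding",
                          chrom = "chr1", strand = "+")
  exons <- tibble::tibble(gene_id = "G", chrom = "chr1",
                          start = c(2500, 6600), end = c(2600, 6800))
  gm <- gene_models(genes, exons)  # TSS 2500, promoter [500, 4501), span [2500, 6800)
  variants <- toy_variants("rv", "chr1", 7500, "breast")
  ann <- structure(list(
    scores = tibble::tibble(variant_id = "rv", vep_class = "none",
                            spliceai_delta = NA_real_, maxentscan = NA_real_,
                            regulome_rank = "2a", regulome_probability = 0.8),
    chromhmm = tibble::tibble(variant_id = character(), biosample = character(),
                              state = character())),
    class = "annotation_scores")
  interactions <- tibble::tibble(
    bait_chrom = "chr1", bait_start = 2000, bait_end = 3000,
    oe_chrom = "chr1", oe_start = 7000, oe_end = 8000,
    cell_line = c("lineA", "lineB"), n_reads = 12, score = 6)
  tads <- tibble::tibble(chrom = "chr1", start = 0, end = 9000)
  list(fragments = fragments, gm = gm, variants = variants, ann = ann,
       interactions = interactions, tads = tads)
}

test_that("distal assignment links regulatory intergenic variants through baited promoters", {
  fx <- make_link_fixture()
  links <- assign_distal(fx$variants, fx$fragments, fx$interactions, fx$gm,
                         fx$ann, tads = fx$tads)
  expect_equal(nrow(links), 1)
  expect_equal(links$gene_id, "G")
  expect_equal(links$cell_lines[[1]], c("lineA", "lineB"))
  expect_true(links$within_tad)

  # sub-threshold regulatory probability kills the link
  ann_low <- fx$ann
  ann_low$scores$regulome_probability <- 0.40
  expect_equal(nrow(assign_distal(fx$variants, fx$fragments, fx$interactions,
                                  fx$gm, ann_low, tads = fx$tads)), 0)

  # bait midpoint outside every TAD -> within_tad FALSE
  tads_far <- tibble::tibble(chrom = "chr1", start = 6000, end = 9000)
  links2 <- assign_distal(fx$variants, fx$fragments, fx$interactions, fx$gm,
                          fx$ann, tads = tads_far)
  expect_equal(nrow(links2), 1)
  expect_false(links2$within_tad)

  # no TADs at all -> message + within_tad FALSE
  expect_message(
    links3 <- assign_distal(fx$variants, fx$fragments, fx$interactions, fx$gm,
                            fx$ann, tads = NULL),
    "No TADs")
  expect_false(links3$within_tad)

  # intronic variant only links in intronic-distal mode
  v_intr <- toy_variants("rv", "chr1", 5000, "breast")  # intron of G, past promoter window
  ints_to_intron <- fx$interactions
  ints_to_intron$oe_start <- 5000; ints_to_intron$oe_end <- 6000
  expect_equal(nrow(assign_distal(v_intr, fx$fragments, ints_to_intron, fx$gm,
                                  fx$ann, tads = fx$tads)), 0)
  expect_equal(nrow(assign_distal(v_intr, fx$fragments, ints_to_intron, fx$gm,
                                  fx$ann, tads = fx$tads,
                                  include_intronic = TRUE)), 1)

  # link set is invariant to interaction order
  fx2 <- make_link_fixture()
  links_rev <- assign_distal(fx2$variants, fx2$fragments,
                             fx2$interactions[2:1, ], fx2$gm, fx2$ann,
                             tads = fx2$tads)
  expect_equal(links, links_rev)
})

test_that("within-TAD interaction counts match the exhaustive pair oracle", {
  withr::local_seed(222)
  cfg <- sim_config(seed = 77, n_chromosomes = 2, chrom_length = 5e6,
                    variants_per_cancer = c(breast = 20, endometrial = 4,
                                            ovarian = 8, prostate = 20),
                    n_genes = 40, interaction_count = 400)
  ann <- simulate_genome_annotation(cfg)
  ints <- simulate_interactions(ann$fragments, ann$gm, ann$tads, cfg)
  asm <- sim_assembly(cfg)
  v <- simulate_variants(cfg)
  regions <- build_mhdcr_regions(build_cancer_regions(v, asm), asm)
  # restrict the oracle to region-contained TADs (the statistic's domain)
  tad_in_region <- GenomicRanges::findOverlaps(
    pleiogene:::iv_to_gr(ann$tads), pleiogene:::iv_to_gr(regions),
    type = "within", select = "first")
  tads_used <- ann$tads[!is.na(tad_in_region), ]
  res <- tad_enrichment(ints, ann$tads, regions, n_perms = 5, rng_seed = 3)
  expect_equal(res$observed, oracle_within_tad(ints, tads_used))
})

test_that("the circularised TAD shuffle handles degenerate geometries", {
  ints <- tibble::tibble(
    bait_chrom = "chr1", bait_start = c(1000, 3000), bait_end = c(1100, 3100),
    oe_chrom = "chr1", oe_start = c(2000, 4200), oe_end = c(2100, 4300),
    cell_line = "L", n_reads = 5, score = 6)
  regions <- tibble::tibble(region_id = 1L, chrom = "chr1",
                            start = 0, end = 5000, cancers = list(c("a", "b")))

  # single TAD covering the whole region: every shift reproduces it
  tad_full <- tibble::tibble(chrom = "chr1", start = 0, end = 5000)
  res <- tad_enrichment(ints, tad_full, regions, n_perms = 100, rng_seed = 1)
  expect_equal(res$observed, 2)
  expect_true(all(res$null_values == 2))
  expect_equal(res$p_empirical, 1)
  expect_false(res$z_defined)

  # no TADs: observed 0, p = 1
  res0 <- tad_enrichment(ints, tad_full[0, ], regions, n_perms = 50,
                         rng_seed = 1)
  expect_equal(res0$observed, 0)
  expect_equal(res0$p_empirical, 1)

  # region shorter than its TAD is impossible by containment, but a direct
  # violation (degenerate region data) is reported
  bad_regions <- tibble::tibble(region_id = 1L, chrom = "chr1",
                                start = 0, end = 3000, cancers = list("a"))
  tad_long <- tibble::tibble(chrom = "chr1", start = 0, end = 3000)
  bad_regions$end <- 2999
  # TAD no longer 'within' the region -> simply ignored, not an error
  expect_silent(tad_enrichment(ints, tad_long, bad_regions, n_perms = 10,
                               rng_seed = 1))
})

test_that("TAD reading enforces disjointness and ibed files round-trip", {
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t0\t1000", "chr1\t500\t1500", "chr1\t2000\t3000"), path)
  expect_message(tads <- read_tads(path), "Dropped 1")
  expect_equal(nrow(tads), 2)

  ints <- tibble::tibble(
    bait_chrom = "chr1", bait_start = 100, bait_end = 200,
    oe_chrom = "chr2", oe_start = 5000, oe_end = 6000,
    cell_line = "L9", n_reads = 42, score = 7.25)
  ipath <- withr::local_tempfile(fileext = ".ibed")
  write_interactions(ints, ipath)
  back <- read_interactions(ipath, cell_line = "L9")
  expect_equal(back, ints)
})
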