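test_that("extended risk intervals clamp at chromosome ends and merge", {
  asm <- genome_assembly("chr1", 1e6)
  v <- toy_variants("rs1", "chr1", 200000, "breast")
  regions <- build_cancer_regions(v, asm, flank = 500000)
  expect_equal(regions$breast,
               genomic_intervals("chr1", 0, 700001))

  # two variants 400 kb apart merge into one interval
  v2 <- toy_variants(c("a", "b"), "chr1", c(200000, 600000), "breast")
  m <- build_cancer_regions(v2, toy_assembly(len = 2e6), flank = 500000)
  expect_equal(nrow(m$breast), 1)

  # LD proxies never seed regions
  v3 <- dplyr::bind_rows(v, toy_variants("proxy", "chr1", 900000, "breast",
                                         is_index = FALSE, r2 = 0.9))
  expect_equal(build_cancer_regions(v3, asm), build_cancer_regions(v, asm))
})

test_that("multi-cancer regions are overlap segments with fused chains", {
  asm <- toy_assembly(len = 2e6)
  per_cancer <- list(
    breast = genomic_intervals("chr1", 0, 700000),
    prostate = genomic_intervals("chr1", 600000, 900000))
  regions <- build_mhdcr_regions(per_cancer, asm)
  expect_equal(nrow(regions), 1)
  expect_equal(c(regions$start, regions$end), c(600000, 700000))
  expect_equal(regions$cancers[[1]], c("breast", "prostate"))

  # chained A-B and B-C overlaps fuse to one region carrying all three;
  # verified against the per-base depth oracle on a 10 kb toy chromosome
  chain <- list(
    A = genomic_intervals("chrA", 0, 5000),
    B = genomic_intervals("chrA", 3000, 8000),
    C = genomic_intervals("chrA", 5000, 10000))
  fused <- build_mhdcr_regions(chain, genome_assembly("chrA", 10000))
  expect_equal(nrow(fused), 1)
  expect_equal(c(fused$start, fused$end), c(3000, 8000))
  expect_equal(fused$cancers[[1]], c("A", "B", "C"))
  want <- oracle_coverage_segments(chain, 2, 10000)
  expect_equal(fused$start, want$start)
  expect_equal(fused$end, want$end)

  # single-cancer input yields nothing
  expect_equal(nrow(build_mhdcr_regions(
    list(A = genomic_intervals("chr1", c(0, 10000), c(100, 10100))), asm)), 0)
})

test_that("region construction is invariant to variant order and duplicates", {
  cfg <- sim_config(seed = 21, n_chromosomes = 2, chrom_length = 1e7,
                    variants_per_cancer = c(breast = 20, endometrial = 4,
                                            ovarian = 8, prostate = 20))
  v <- simulate_variants(cfg)
  asm <- sim_assembly(cfg)
  r1 <- build_mhdcr_regions(build_cancer_regions(v, asm), asm)
  withr::local_seed(707)
  v2 <- dplyr::bind_rows(v[sample.int(nrow(v)), ], v[3, ])
  r2 <- build_mhdcr_regions(build_cancer_regions(v2, asm), asm)
  expect_equal(r1, r2)
})

test_that("signal counts equal the nested-loop oracle and count distinct signals", {
  asm <- toy_assembly(len = 2e6)
  regions <- tibble::tibble(region_id = 1L, chrom = "chr1",
                            start = 0, end = 1e6,
                            cancers = list(c("breast", "prostate")))
  v <- toy_variants(paste0("rs", 1:3), "chr1", c(100, 200, 300), "breast",
                    signal_id = c("s1", "s1", "s2"))
  counted <- count_signals(regions, v)
  expect_equal(counted$signal_counts[[1]], c(breast = 2L))

  # empty region
  v_out <- toy_variants("rs9", "chr1", 1.5e6, "breast")
  expect_equal(length(count_signals(regions, v_out)$signal_counts[[1]]), 0)

  # random instance vs oracle
  withr::local_seed(808)
  regions_r <- tibble::tibble(
    region_id = 1:3, chrom = c("chr1", "chr1", "chr2"),
    start = c(0, 5e5, 2e5), end = c(3e5, 9e5, 8e5),
    cancers = list("x", "x", "x"))
  vr <- toy_variants(paste0("v", 1:60),
                     sample(c("chr1", "chr2"), 60, replace = TRUE),
                     sample.int(1e6, 60) - 1,
                     sample(hdc_cancers(), 60, replace = TRUE),
                     signal_id = paste0("sig", sample.int(20, 60, replace = TRUE)),
                     is_index = sample(c(TRUE, FALSE), 60, replace = TRUE))
  got <- signal_count_table(regions_r, vr) |>
    dplyr::arrange(region_id, cancer)
  want <- oracle_signal_counts(regions_r, vr) |>
    dplyr::arrange(region_id, cancer)
  expect_equal(as.data.frame(got), as.data.frame(want))
})

test_that("combination summaries partition the region set", {
  regions <- tibble::tibble(
    region_id = 1:3, chrom = "chr1", start = c(0, 10, 20), end = c(5, 15, 25),
    cancers = list(c("A", "B"), c("A", "B"), c("A", "B", "C")))
  s <- combination_summary(regions)
  expect_equal(s$by_combination$n[s$by_combination$combination == "A+B"], 2)
  expect_equal(s$by_combination$n[s$by_combination$combination == "A+B+C"], 1)
  expect_equal(sum(s$by_combination$n), nrow(regions))
  expect_equal(sum(s$by_cardinality$n), nrow(regions))
})

test_that("growing the flank never drops cancers from surviving regions", {
  cfg <- sim_config(seed = 31, n_chromosomes = 2, chrom_length = 2e7,
                    variants_per_cancer = c(breast = 30, endometrial = 6,
                                            ovarian = 10, prostate = 30))
  v <- simulate_variants(cfg)
  asm <- sim_assembly(cfg)
  small <- build_mhdcr_regions(build_cancer_regions(v, asm, flank = 3e5), asm)
  large <- build_mhdcr_regions(build_cancer_regions(v, asm, flank = 6e5), asm)
  # every small-flank region is contained in a large-flank region whose
  # cancer set is a superset
  for (i in seq_len(nrow(small))) {
    container <- which(large$chrom == small$chrom[i] &
                         large$start <= small$start[i] &
                         large$end >= small$end[i])
    expect_length(container, 1)
    expect_true(all(small$cancers[[i]] %in% large$cancers[[container]]))
  }
})
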