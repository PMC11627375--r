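# Fixture: one region holding a gene with a breast promoter variant and a
# prostate distal regulatory variant looping to the gene promoter within a TAD
# (the two-channel candidate archetype).
make_call_fixture <- function() {
  regions <- tibble::tibble(region_id = 1L, chrom = "chr1",
                            start = 0, end = 50000,
                            cancers = list(c("breast", "prostate")))
  genes <- tibble::tibble(
    gene_id = c("G1", "G2"), name = c("G1", "G2"),
    biotype = "protein_coding", chrom = "chr1", strand = "+")
  exons <- tibble::tibble(
    gene_id = c("G1", "G1", "G2", "G2"), chrom = "chr1",
    start = c(10000, 16000, 30000, 36000), end = c(10200, 16500, 30200, 36500))
  gm <- gene_models(genes, exons)  # G1 TSS 10000, G2 TSS 30000
  variants <- toy_variants(
    c("v_prom_breast", "v_distal_prostate", "v_single"),
    "chr1", c(8500, 22500, 29000),
    c("breast", "prostate", "ovarian"))
  ann <- structure(list(
    scores = tibble::tibble(
      variant_id = c("v_prom_breast", "v_distal_prostate", "v_single"),
      vep_class = "none",
      spliceai_delta = NA_real_, maxentscan = NA_real_,
      regulome_rank = c("4", "1b", "2a"),
      regulome_probability = c(0.2, 0.9, 0.7)),
    chromhmm = tibble::tibble(
      variant_id = c("v_prom_breast", "v_distal_prostate"),
      biosample = c("breast_1", "prostate_1"),
      state = c("TssA", "EnhA1"))),
    class = "annotation_scores")
  distal_links <- tibble::tibble(
    variant_id = "v_distal_prostate", gene_id = "G1",
    cell_lines = list("prostate_line1"), within_tad = TRUE)
  list(regions = regions, gm = gm, variants = variants, ann = ann,
       distal_links = distal_links)
}

test_that("a gene with promoter and distal evidence from two cancers is called", {
  fx <- make_call_fixture()
  calls <- call_candidate_genes(fx$regions, fx$variants, fx$ann,
                                fx$distal_links, fx$gm)
  expect_equal(calls$candidates$gene_id, "G1")
  expect_equal(calls$candidates$cancers[[1]], c("breast", "prostate"))
  expect_equal(calls$candidates$evidence,
               "breast:promoter;prostate:distal_reg_within_tad")
  expect_true(calls$candidates$chromhmm_support)
  expect_equal(calls$candidates$region_ids[[1]], 1L)
  # audit trail resolves every category to a variant
  expect_setequal(calls$audit$variant_id,
                  c("v_prom_breast", "v_distal_prostate"))

  # a non-within-TAD link contributes nothing: gene drops to one cancer
  links_out <- fx$distal_links
  links_out$within_tad <- FALSE
  none <- call_candidate_genes(fx$regions, fx$variants, fx$ann, links_out,
                               fx$gm)
  expect_equal(nrow(none$candidates), 0)

  # a link to a gene missing from the models is an error
  links_bad <- fx$distal_links
  links_bad$gene_id <- "GHOST"
  expect_error(call_candidate_genes(fx$regions, fx$variants, fx$ann,
                                    links_bad, fx$gm), "GHOST")
})

test_that("coding-only calls are a subset of full-mode calls", {
  fx <- make_call_fixture()
  full <- call_candidate_genes(fx$regions, fx$variants, fx$ann,
                               fx$distal_links, fx$gm)
  coding <- call_candidate_genes(fx$regions, fx$variants, fx$ann,
                                 fx$distal_links, fx$gm,
                                 channels = c("coding", "promoter", "splicing"))
  expect_true(all(coding$candidates$gene_id %in% full$candidates$gene_id))
  expect_equal(nrow(coding$candidates), 0)  # distal channel was load-bearing

  # and on a simulated dataset, as a general monotonicity property
  d <- simulate_dataset(sim_config(seed = 13, n_true_genes = 8,
                                   pleiotropy_fraction = 0))
  asm <- d$assembly
  regions <- build_mhdcr_regions(build_cancer_regions(d$variants, asm), asm)
  full_s <- call_candidate_genes(regions, d$variants, d$annotation,
                                 tibble::tibble(variant_id = character(),
                                                gene_id = character(),
                                                cell_lines = list(),
                                                within_tad = logical()),
                                 d$gm)
  coding_s <- call_candidate_genes(regions, d$variants, d$annotation, NULL,
                                   d$gm,
                                   channels = c("coding", "promoter",
                                                "splicing"))
  expect_true(all(coding_s$candidates$gene_id %in% full_s$candidates$gene_id))
})

test_that("lncRNA calling uses exon/promoter/regulatory categories", {
  regions <- tibble::tibble(region_id = 1L, chrom = "chr1",
                            start = 0, end = 1e6,
                            cancers = list(c("ovarian", "prostate")))
  gm <- toy_gene_models()  # lnc1: exon [400000, 401000), TSS 400000
  v <- toy_variants(c("v_ex_ov", "v_prom_pr"), "chr1",
                    c(400500, 398500), c("ovarian", "prostate"))
  ann <- structure(list(
    scores = tibble::tibble(variant_id = v$variant_id, vep_class = "none",
                            spliceai_delta = NA_real_, maxentscan = NA_real_,
                            regulome_rank = "4",
                            regulome_probability = c(0.1, 0.2)),
    chromhmm = tibble::tibble(variant_id = character(),
                              biosample = character(), state = character())),
    class = "annotation_scores")
  calls <- call_candidate_lncrnas(regions, v, ann, NULL, gm)
  expect_equal(calls$candidates$gene_id, "lnc1")
  expect_equal(calls$candidates$evidence, "ovarian:exon;prostate:promoter")

  # two cancers but non-qualifying evidence -> not emitted
  v2 <- toy_variants(c("i1", "i2"), "chr1", c(205000, 210000),
                     c("ovarian", "prostate"))  # introns of gminus
  ann2 <- ann
  ann2$scores$variant_id <- v2$variant_id
  calls2 <- call_candidate_lncrnas(regions, v2, ann2, NULL, gm)
  expect_equal(nrow(calls2$candidates), 0)
})

test_that("Fisher enrichment matches the hypergeometric-sum oracle", {
  # worked 2x2: a=4, b=6, c=10, d=80
  background <- paste0("g", 1:100)
  candidates <- background[1:10]
  category <- c(background[1:4], background[11:20])
  res <- fisher_enrichment(candidates, category, background)
  expect_equal(unname(res$table[1, 1]), 4)
  expect_equal(res$odds_ratio, 16 / 3)
  expect_equal(res$p_fisher, oracle_fisher_p(4, 6, 10, 80))

  # category disjoint from background genes entirely
  res0 <- fisher_enrichment(candidates, "elsewhere", background)
  expect_false(res0$or_defined)
  expect_equal(res0$p_fisher, 1)

  expect_error(fisher_enrichment("g1", "g1", character()), "non-empty")

  # sweep of small tables (margins <= 30) against the oracle
  withr::local_seed(333)
  for (rep in 1:50) {
    a <- sample(0:10, 1); b <- sample(0:10, 1)
    cc <- sample(0:10, 1); d <- sample(1:10, 1)
    bg <- paste0("x", seq_len(a + b + cc + d))
    cand <- bg[seq_len(a + b)]
    cat_m <- c(bg[seq_len(a)], bg[a + b + seq_len(cc)])
    if (a + b == 0) next
    got <- fisher_enrichment(cand, cat_m, bg)
    expect_equal(got$p_fisher, oracle_fisher_p(a, b, cc, d),
                 tolerance = 1e-10)
  }
})

test_that("matched permutation z flags degenerate nulls and matches expectation", {
  pools <- list(`1` = paste0("a", 1:10), `2` = paste0("b", 1:8))
  cands <- c("a1", "a2", "b1")
  cand_regions <- c("1", "1", "2")

  # category covers every pool member: all draws equal the observed count
  res_all <- matched_permutation_z(cands, cand_regions,
                                   unlist(pools), pools,
                                   n_perms = 200, rng_seed = 4)
  expect_false(res_all$z_defined)
  expect_equal(res_all$observed, 3)

  # empty category: observed 0, null all 0
  res_none <- matched_permutation_z(cands, cand_regions, character(), pools,
                                    n_perms = 200, rng_seed = 4)
  expect_equal(res_none$observed, 0)
  expect_true(all(res_none$null_values == 0))
  expect_false(res_none$z_defined)

  # pool smaller than the candidate draw is an error naming the region
  expect_error(matched_permutation_z(c("a1", "a2"), c("9", "9"),
                                     "a1", list(`9` = "a1"),
                                     n_perms = 10), "Region 9")

  # null mean approaches the hypergeometric expectation
  category <- c(paste0("a", 1:4), paste0("b", 1:2))  # 4/10 and 2/8 in category
  res <- matched_permutation_z(cands, cand_regions, category, pools,
                               n_perms = 10000, rng_seed = 5)
  expectation <- 2 * 4 / 10 + 1 * 2 / 8
  var_hyper <- 2 * (4 / 10) * (6 / 10) * (10 - 2) / (10 - 1) +
    1 * (2 / 8) * (6 / 8) * (8 - 1) / (8 - 1)
  se <- sqrt(var_hyper / 10000)
  expect_lt(abs(mean(res$null_values) - expectation), 3 * se)

  # label-permutation mode runs and reports the same observed statistic
  res_lab <- matched_permutation_z(cands, cand_regions, category, pools,
                                   n_perms = 500, rng_seed = 6,
                                   null = "label-permutation")
  expect_equal(res_lab$observed, res$observed)
})
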