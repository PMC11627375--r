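#!/usr/bin/env Rscript

# Stage 7 — are candidates enriched for known cancer genes / drug targets?
#
# Fisher's exact test against the background of all protein-coding genes at
# the multi-cancer regions, plus a region-matched permutation z-score
# (random gene sets matched to the number of candidates per region).

suppressMessages(library(pleiogene))

d <- load_dataset("results/data")
res <- run_pipeline(d, pipeline_params(n_perms_matched = 10000, seed = 17),
                    run_cluster_test = FALSE, run_tad_test = FALSE)

for (cat_name in names(res$enrichment)) {
  e <- res$enrichment[[cat_name]]
  cat("\n==", cat_name, "==\n")
  print(e$fisher)
  if (!is.null(e$matched)) print(e$matched)
}

dir.create("results", showWarnings = FALSE)
out <- lapply(res$enrichment, function(e) {
  list(odds_ratio = e$fisher$odds_ratio,
       odds_ratio_mle = e$fisher$odds_ratio_mle,
       p_fisher = e$fisher$p_fisher,
       matched_z = if (!is.null(e$matched)) e$matched$z else NULL,
       matched_n_perms = if (!is.null(e$matched)) e$matched$n_perms else NULL)
})
jsonlite::write_json(out, "results/enrichment.json", auto_unbox = TRUE,
                     digits = NA, null = "null")
cat("\nEnrichment summary written to results/enrichment.json\n")
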