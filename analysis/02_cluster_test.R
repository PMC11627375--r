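#!/usr/bin/env Rscript

# Stage 2 — do risk variants of different cancers co-localise?
#
# Single-linkage clusters of index variants within 100 kb windows; a cluster
# is multi-trait when it holds >= 2 cancers. Significance from 10,000
# chromosome-preserving uniform shuffles (raise n_perms for finer p-values).

suppressMessages(library(pleiogene))

d <- load_dataset("results/data")
res <- clustering_permutation_test(
  dplyr::filter(d$variants, is_index), d$assembly,
  max_gap = 100000, n_perms = 10000, rng_seed = 1)
print(res)

dir.create("results", showWarnings = FALSE)
jsonlite::write_json(
  list(observed = res$observed, z = res$z, p_empirical = res$p_empirical,
       p_is_upper_bound = res$p_is_upper_bound, n_perms = res$n_perms,
       seed = res$seed),
  "results/cluster_test.json", auto_unbox = TRUE, digits = NA)
cat("Result written to results/cluster_test.json\n")
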