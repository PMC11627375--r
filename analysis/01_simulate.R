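#!/usr/bin/env Rscript

# Stage 1 — generate the synthetic study inputs.
#
# Produces a dataset under the default study conditions (index-variant counts
# 196/17/60/258 across four hormone-dependent cancers, half of the non-breast
# variants co-located within 50 kb of a breast variant, TAD-enriched
# promoter-capture interactions), plants ten true pleiotropic genes with
# qualifying promoter variants from two cancers each, and writes every input
# file the downstream stages read (plus the truth table for stage 6).

suppressMessages(library(pleiogene))

outdir <- "results/data"
cfg <- sim_config(seed = 20260923, n_true_genes = 10)
d <- simulate_dataset(cfg)
write_dataset(d, outdir)

cat("Simulated dataset written to", outdir, "\n")
cat("  variants:     ", nrow(d$variants), "\n")
cat("  genes:        ", nrow(d$gm$genes), "\n")
cat("  fragments:    ", nrow(d$fragments), "\n")
cat("  TADs:         ", nrow(d$tads), "\n")
cat("  interactions: ", nrow(d$interactions), "\n")
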