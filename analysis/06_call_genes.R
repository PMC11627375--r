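#!/usr/bin/env Rscript

# Stage 6 — call candidate multi-cancer genes and lncRNAs.
#
# A gene is a candidate when >= 2 cancers contribute qualifying evidence:
# coding consequence, promoter variant, predicted splice-altering intronic
# variant, regulatory intronic variant, or a distal regulatory variant
# looping to the promoter within a TAD.

suppressMessages(library(pleiogene))

d <- load_dataset("results/data")
regions <- build_mhdcr_regions(build_cancer_regions(d$variants, d$assembly),
                               d$assembly)
ints <- filter_interactions(d$interactions)
links <- assign_distal(d$variants, d$fragments, ints, d$gm, d$annotation,
                       tads = d$tads)

calls <- call_candidate_genes(regions, d$variants, d$annotation, links, d$gm,
                              cosmic_genes = d$categories$cosmic,
                              drug_target_genes = d$categories$drug_target)
coding_only <- call_candidate_genes(regions, d$variants, d$annotation, links,
                                    d$gm, channels = c("coding", "promoter",
                                                       "splicing"))
lnc <- call_candidate_lncrnas(regions, d$variants, d$annotation, links, d$gm)

cat("Candidate genes, coding/promoter/splicing channels only:",
    nrow(coding_only$candidates), "\n")
cat("Candidate genes, all channels:", nrow(calls$candidates), "\n")
cat("Candidate lncRNAs:", nrow(lnc$candidates), "\n")
if (nrow(calls$candidates)) {
  cat("With ChromHMM regulatory support:",
      sum(calls$candidates$chromhmm_support), "\n")
  cat("Known cancer genes among candidates:",
      sum(calls$candidates$cosmic), "\n")
}

dir.create("results", showWarnings = FALSE)
tab <- tibble::tibble(
  gene_id = calls$candidates$gene_id,
  name = calls$candidates$name,
  regions = vapply(calls$candidates$region_ids, paste, character(1),
                   collapse = ","),
  cancers = vapply(calls$candidates$cancers, paste, character(1),
                   collapse = ","),
  evidence = calls$candidates$evidence,
  chromhmm_support = calls$candidates$chromhmm_support,
  cosmic = calls$candidates$cosmic,
  drug_target = calls$candidates$drug_target)
readr::write_tsv(tab, "results/candidates.tsv")
readr::write_tsv(calls$audit, "results/evidence_audit.tsv")
cat("Candidate tables written to results/\n")

if (nrow(d$truth)) {
  rec <- score_recovery(calls, d$truth)
  cat("Planted-truth recovery: recall", rec$recall,
      "precision", rec$precision, "\n")
}
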