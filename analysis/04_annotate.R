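#!/usr/bin/env Rscript

# Stage 4 — classify variant locations and apply the score thresholds.
#
# Each variant is classified per gene (exon > promoter > intron precedence;
# promoter = TSS +/- 2 kb) and summarised to a single class. Threshold
# verdicts: SpliceAI delta >= 0.2 or |MaxEntScan| > 0 (splice-altering),
# RegulomeDB probability > 0.55 (regulatory).

suppressMessages(library(pleiogene))
suppressMessages(library(dplyr))

d <- load_dataset("results/data")
loc <- classify_location(d$variants, d$gm, promoter_flank = 2000)
summ <- summarize_location(d$variants, loc)

cat("Variant location breakdown:\n")
print(table(summ$location_summary))

sc <- d$annotation$scores
verdicts <- summ |>
  left_join(sc, by = "variant_id") |>
  mutate(regulatory = is_regulatory(regulome_probability),
         splice_altering = location_summary == "intronic" &
           is_splice_altering(spliceai_delta, maxentscan),
         coding_category = coding_evidence(vep_class))
cat("Regulatory (RegulomeDB > 0.55):", sum(verdicts$regulatory), "\n")
cat("Potential splice-altering intronic variants:",
    sum(verdicts$splice_altering), "\n")
cat("Variants with retained coding consequences:",
    sum(!is.na(verdicts$coding_category) &
          verdicts$location_summary == "exonic"), "\n")

dir.create("results", showWarnings = FALSE)
readr::write_tsv(loc, "results/variant_gene_location.tsv")
readr::write_tsv(verdicts, "results/variant_verdicts.tsv")
cat("Annotation tables written to results/\n")
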