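---
title: "Mapping multi-cancer risk regions and candidate pleiotropic genes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping multi-cancer risk regions and candidate pleiotropic genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(pleiogene)
```

## The model

Hormone-dependent cancers — breast, endometrial, ovarian and prostate —
share endocrine aetiology, and their GWAS risk variants concentrate in
common genomic neighbourhoods more often than chance placement would allow.
The pipeline in this package formalises that observation and follows it to
candidate target genes in five steps: (i) test whether variants of different
cancers co-cluster spatially; (ii) define multi-cancer risk regions by
overlap of flank-extended per-cancer intervals; (iii) classify every
candidate variant against gene models and threshold its functional scores;
(iv) assign distal regulatory variants to target genes through
promoter-capture Hi-C (PCHiC) interactions, prioritised by topologically
associating domains (TADs); and (v) call genes supported by at least two
cancers, with enrichment tests against curated gene categories.

All coordinates are 0-based half-open (BED convention) internally and in
every BED output; 1-based coordinates appear only in GFF3 files, converted
at the boundary. Unknown chromosomes and trait labels are hard errors rather
than silent drops: a silently lost variant would corrupt the permutation
counts downstream.

## Clustering test

Variants are clustered per chromosome by single linkage with a maximum gap,
default 100 kb: consecutive position-sorted variants belong to one cluster
when their gap is at most `max_gap`. This reproduces `bedtools cluster -d`
semantics rather than fixed genomic tiles; a `method = "tiling"` mode (fixed
windows of width `max_gap`) is provided for sensitivity analysis, since the
two disagree exactly when a pair of nearby variants straddles a window
boundary. The statistic is the number of clusters containing two or more
distinct cancer labels.

The null hypothesis is positional independence given the chromosomal
distribution: each permutation re-places every variant (all four trait sets
jointly) at an independent uniform position on its own chromosome, exactly
conserving per-(chromosome, cancer) counts. No exclusion regions are applied
by default; an `exclude` argument (e.g. assembly gaps) redraws positions by
rejection when supplied. The empirical p-value follows the resampling
convention `#{null ≥ observed} / n_perms` without add-one smoothing, so it
matches the count-based definition exactly; a `smoothed` option computes
`(k+1)/(n+1)` for users who prefer the never-zero estimator. When the count
is zero the p-value is reported as the upper bound `1/n_perms` with an
explicit flag. The z-score standardises the observed count against the null
and is flagged undefined when the null is degenerate (zero spread).

The permutation stream is generated after canonicalising the variant order
(chromosome rank, position, cancer, id), so the p-value is invariant to how
the input file happened to be sorted. Index variants are the intended input
(the proxies of one signal would otherwise cluster trivially); the caller
controls this by filtering on `is_index`.

## Region construction

Each index variant is extended by `flank` (default 0.5 Mb) on either side —
the closed position plus flank on both sides, i.e. the half-open interval
`[pos − flank, pos + flank + 1)` — clamped at chromosome ends rather than
discarded, so telomere-proximal variants still seed regions. Per-cancer
intervals are merged (book-ended intervals merge, the `bedtools merge`
default). Multi-cancer regions are the maximal segments covered by at least
`min_cancers` (default 2) distinct cancers; qualifying segments that touch
are fused into a single region even when the contributing pair changes along
the segment, and the region's cancer set is every cancer whose extended
interval overlaps it. Regions are numbered in genome order. LD proxies do
not extend regions; independent-signal counts per region count distinct
`signal_id`s of index variants inside the region.

## Variant annotation

Per (variant, gene) pair the location class is decided with the precedence
exon > promoter > intron: exonic if the variant base lies in any exon of the
gene; else promoter if within TSS ± 2 kb (both boundaries inclusive; the TSS
is the 5'-most exon boundary respecting strand); else intronic if inside the
gene span. A variant can be promoter of one gene and intronic of another;
a variant with no gene context is intergenic. For single-class summaries the
same precedence is applied across genes.

Score thresholds are pure functions of the record:

* splice-altering (intronic variants): SpliceAI delta ≥ 0.2 (inclusive) OR
  |MaxEntScan| > 0. The MaxEntScan rule is applied to the provided score
  column as given; whether that column holds a raw or a reference/alternate
  difference score is the data provider's convention and is deliberately not
  reinterpreted here. The OR combination is used — either predictor
  suffices.
* regulatory: RegulomeDB probability strictly greater than 0.55 (the
  genome-wide median); exactly 0.55 does not qualify.
* coding: VEP classes frameshift, missense, synonymous, 5'UTR and 3'UTR are
  retained as evidence categories; UTR classes come from the score table
  rather than being recomputed from gene models.
* ChromHMM: a configurable set of active states (default the TSS- and
  enhancer-class labels of an 18-state model: TssA, TssFlnk, TssFlnkU,
  TssFlnkD, EnhA1, EnhA2, EnhG1, EnhG2, EnhWk) in a relevant biosample.

Missing scores never qualify under any rule: absent evidence is treated
conservatively as no evidence, never imputed.

## PCHiC linking and the TAD test

Interactions with CHiCAGO score ≥ 5 (inclusive) are high-confidence. A
distal link (variant → gene) requires: the variant is intergenic (an
`include_intronic` switch adds intronic-distal looping, off by default since
the distal category is defined for variants outside any gene), it passes the
regulatory threshold, and its containing restriction fragment is the other
end of an interaction whose bait fragment overlaps the gene's promoter.
Cell lines are aggregated over supporting interactions. "Within TAD" is
decided on fragment midpoints — fragments can straddle TAD boundaries and
the midpoint is the least surprising single-point rule — and a link is
within-TAD when any supporting interaction has both midpoints in one TAD.

The TAD enrichment test counts interactions with both midpoints inside one
and the same TAD, restricted to TADs fully contained in a multi-cancer
region. The null shifts each TAD independently by a uniform offset modulo
the region length with wrap-around (the region is circularised: a TAD pushed
past the region end re-enters at the region start, occupying a suffix and a
prefix but still counting as one TAD). This conserves every TAD's length
exactly; shifted TADs may overlap each other, which is the price of
independent placement. Interactions spanning two regions are attributed to
the region of both midpoints (a pair inside a TAD is automatically inside
that TAD's region). The default is 10,000 permutations; the test is cheap
enough that 10^5 is practical when finer p-resolution is wanted.

A caution that matters for interpretation on real data: when TADs tile a
region with no gaps, this null is intrinsically anti-conservative, because
independently shifted TADs overlap one another and lose union coverage
relative to the observed disjoint arrangement — the observed count then
exceeds the null mean even when interactions ignore TADs entirely. The bias
shrinks with TAD sparsity and with the number of TADs per region. The
synthetic generator therefore produces TADs as sparse domains separated by
exponential boundary gaps (domain mean 200 kb, gap mean 800 kb, about one
domain per typical region), a geometry under which the calibration tests
show the test's p-values are uniform when interactions carry no TAD
structure.

## Candidate gene calling

Evidence categories per (gene, cancer): coding consequences on exonic
variants (for lncRNAs, exonic location alone gives category `exon`);
`promoter`; `splicing` (protein-coding only); `intronic_regulatory`;
`distal_reg_within_tad`. A gene is a candidate when at least two distinct
cancers contribute at least one qualifying variant each — presence/absence,
no variant-count weighting. Variants outside every region are ignored;
candidate genes are attributed to every region they overlap. The full
audit trail (gene, cancer, category, variant) is returned and written, so
every call is mechanically traceable to its variants. Restricting channels
to coding/promoter/splicing reproduces the coding-first call, which is by
construction a subset of the all-channels call.

ChromHMM support is aggregated over a gene's evidence variants; when a
biosample-to-cancer mapping is supplied, only biosamples of the gene's
evidence cancers count. COSMIC-style and drug-target flags are joined from
category lists.

## Enrichment

Fisher's exact test (one-sided, greater) compares candidates against the
background of all protein-coding genes at the regions. The reported odds
ratio is the sample OR `ad/bc` (the conditional-MLE OR from `fisher.test`
is also returned); when a cell is zero the Haldane–Anscombe +0.5 correction
is applied and flagged, and the OR is undefined when the category is absent
from candidates and background alike. The matched-set permutation draws,
per region, as many genes (without replacement) from the region's gene pool
as the region contributed candidates, and z-scales the null; a
label-permutation mode (category labels permuted over the pooled genes) is
available as an alternative null. A candidate overlapping several regions is
attributed to its first region for matching.

One structural caveat: when a region's pool contains few genes beyond the
candidates themselves (common in sparse synthetic genomes and possible at
gene-poor real loci), the matched draw is forced to re-select the
candidates and the z-score shrinks toward zero by construction. The Fisher
test does not share this degeneracy; both are reported.

## The synthetic-data generator

The generator emulates the study conditions end-to-end and is itself
first-class, tested code:

* **Variants** — per-cancer index counts default to 196 (breast),
  17 (endometrial), 60 (ovarian), 258 (prostate), the sizes of the real
  index sets. Breast variants are uniform; each other cancer's variant is,
  with probability `pleiotropy_fraction` (default 0.5), placed within
  `co_locate_window` (50 kb) of a random breast variant. Setting the
  fraction to 0 gives the calibration null.
* **Genome** — 8 chromosomes × 50 Mb by default. This is deliberately
  smaller than a human genome, so variant density (and hence baseline
  cluster counts) is higher than in real data; calibration and power
  properties, not absolute counts, are the design targets.
* **Genes** — 2–10 exons, random strand with strand-consistent TSS,
  non-overlapping with a 10 kb pad so a promoter never touches a
  neighbouring gene; 20% lncRNA.
* **Fragments** — exponential-ish lengths, mean 4 kb (HindIII scale),
  tiling each chromosome exactly. An in-silico digest of a provided FASTA
  (cutting at every AAGCTT site) is available as an alternative.
* **Scores** — RegulomeDB probabilities follow a two-component mixture so a
  configurable fraction (default 0.3) of noncoding variants exceed 0.55;
  sparse VEP consequences on exonic variants; SpliceAI/MaxEntScan mostly
  missing with occasional qualifying values; ChromHMM states over 12
  biosamples (3 breast, 1 endometrial, 3 ovarian, 5 prostate, mirroring the
  real tissue panel) with active states concentrated in regulatory variants'
  own cancers.
* **Interactions** — baits are exactly the promoter-overlapping fragments;
  other ends at a geometric fragment offset (mean 25 fragments ≈ 100 kb);
  pairs not sharing a TAD are thinned by `1/within_tad_enrichment`
  (default 3; 1 = no TAD structure). Scores are drawn so ~85% pass the
  confidence threshold.
* **Planted truth** — `n_true_genes` protein-coding genes receive promoter
  index variants from two random cancers each (placed upstream of the first
  exon so the promoter class is unambiguous), replacing background variants
  so per-cancer totals are conserved; planted variants always qualify as
  regulatory and chromatin-active. Recovery (recall/precision against the
  truth table) is scored with the background co-location switched off, so
  that recovered genes are attributable to the planted signal rather than
  to incidental co-location. Category lists are drawn with elevated
  membership rates for truth genes (drug targets 0.4 vs 0.15; cancer-census
  0.3 vs 0.08), emulating the enrichment observed among real multi-cancer
  candidates.

Everything is a pure function of (configuration, seed); stage seeds are
derived deterministically from the master seed.

What passing tests on this generator do **not** show about real data: the
generator has no LD structure (each variant is its own signal), no
sequence-level realism, uniform variant placement outside the planted
structure, equal chromosome lengths, and planted evidence of a single clean
type (promoter variants). Real candidate calls depend on LD-expanded proxy
sets, annotation quality and capture design in ways the synthetic data
cannot probe.

## Numerical and testing choices

Test problem sizes are chosen to keep the suite fast while leaving the
statistics meaningful: calibration uses 200 generator replicates at 500
permutations for the clustering test (Kolmogorov–Smirnov uniformity check)
and 100 replicates at 300 permutations for the TAD test on a reduced
geometry with study-like region density; power checks use 10,000
permutations (clustering) and 2,000 (TAD, at 1,000 interactions). The
brute-force oracles (per-base occupancy and depth, O(n²) pairwise linkage
with transitive closure, exhaustive interaction × TAD membership,
hypergeometric tail summation, rank-then-Pearson correlation) are
implemented in the test helpers, independent of the package's code paths.

Ties in the empirical p-value count as `≥ observed` (the conservative
direction). Degenerate nulls (zero spread) yield a flagged undefined z with
a still-valid p. Book-ended intervals merge everywhere. Duplicate rsIDs
shared between cancers are stored as one record per (variant, cancer) pair.
The two permutation-count conventions in circulation for the TAD and
category tests (10^4 vs 10^5) are both supported through `n_perms`
arguments; defaults follow the smaller, which is sufficient for the
p-values at stake here.

## Known limitations

* The clustering null is genome-uniform per chromosome; annotation-matched
  nulls (GC, gene density, accessible chromatin) are out of scope, so on
  real data the test detects co-location relative to uniform placement,
  not relative to a shared open-chromatin landscape.
* LD-aware shuffling and LD-based region boundaries are not implemented;
  region boundaries are purely positional.
* The TAD test's sensitivity to TAD-map density (see above) means its
  p-value on a gapless TAD tiling should be interpreted with care.
* Candidate calling requires the interacting cell line only to exist, not
  to match the variant's cancer; cell lines are reported per link so users
  can post-filter.
* Genes overlapping two regions are attributed to all of them for
  reporting, and to the first for matched-set sampling.
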