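---
title: "Calling candidate enhancers from differential accessibility and combinatorial TF binding"
author: "ocre"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling candidate enhancers from differential accessibility and combinatorial TF binding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ocre)
```

## The analysis

`ocre` operationalises a common regulatory-genomics design: two related
cell populations (here called condition A, e.g. notochord progenitors, and
condition B, e.g. mesoderm progenitors) are profiled by ATAC-seq; regions
gaining accessibility in condition A and lying away from promoters are
candidate enhancers; overlap with the binding of lineage transcription
factors (T measured in a progenitor state, T and Foxa2 measured in the
target state) classifies each candidate into one of the seven possible
binding combinations; finally candidates are tied to nearby genes and
summarised against condition-specific expression.

The stages, and the operations behind them:

1. **Fragments.** Paired-end records become fragments spanning the
   outermost mate coordinates (`fragments_from_pairs()`), capped at a
   maximum insert of 2000 bp (the usual upper bound set when mapping ATAC
   libraries). Exact duplicates — same chromosome, start and end — are
   collapsed (`deduplicate_fragments()`), and chrY/chrM fragments are
   dropped (`drop_chromosomes()`): chrY because of its repetitive content,
   chrM because it is uninformative for chromatin accessibility.
2. **Differential accessibility.** Chromosomes are tiled with 1 kb windows
   every 100 bp; each window's fragment counts in the two libraries form a
   2x2 table against the library totals, tested with the likelihood-ratio
   (G) test

   $$G = 2 \sum_{\text{cells}} O \,\ln(O/E), \qquad G \sim \chi^2_1
   \text{ under the null},$$

   with expected values from the table margins and the convention
   $0\ln 0 = 0$; no continuity correction is applied. P-values are
   Benjamini–Hochberg adjusted across all tested windows; windows with
   $q \le 0.05$ and a library-size-normalised fold change of at least 2
   are kept, and significant same-direction windows closer than one step
   are merged into regions (`detect_differential()`). Regions overlapping
   a promoter — ±5 kb around any transcription start site — are then
   removed wholesale (`exclude_promoters()`).
3. **Binding categories.** The three TF peak sets are cleansed of peaks in
   blacklist regions (mapping-artifact intervals), clustered by transitive
   overlap, and each cluster is labelled with the combination of sources
   contributing to it (`combinatorial_profiles()`). The single-bp anchor
   of a cluster is the summit of its peak from the highest-precedence
   source present (T-progenitor > T-target > Foxa2); anchors falling
   inside a promoter-distal region gaining accessibility in condition A
   define the enhancer table (`anchor_maxima()`, `intersect_maxima()`).
4. **Genes.** Condition-specific genes are those whose FPKM exceeds the
   other condition's by ≥ 3-fold at *both* developmental stages
   (`specific_genes()`). Each enhancer anchor is assigned target genes by
   location: intergenic anchors go to the closest gene on each side; genic
   anchors go to every host gene plus the two flanking genes
   (`assign_target_genes()`). Conversely, a gene's *domain* — from the
   outer boundary of its upstream neighbour's body to the outer boundary
   of its downstream neighbour's — collects the enhancers associated with
   it (`gene_domain()`, `associate()`), and per-gene sets of enhancer
   categories are tabulated UpSet-style (`upset_table()`).

## Parameters that matter

| parameter | default | unit | why |
|---|---|---|---|
| `window`, `step` | 1000, 100 | bp | ATAC signal is broad relative to nucleosome scale; a 1 kb window at 100 bp step localises region edges to ~100 bp |
| `alpha` | 0.05 | — | conventional FDR level for the window screen |
| `min_fold` | 2 | ratio | discards statistically significant but biologically negligible shifts at high depth |
| `promoter_flank` | 5000 | bp | promoter-proximal accessibility reflects transcription, not enhancer activity |
| `max_insert` | 2000 | bp | pairs longer than the mapping bound are artefacts |
| `specific_fold` | 3 | ratio | two-stage, both-stage 3-fold criterion for condition-specific genes |
| `expression_floor` | 1 | FPKM | genes never reaching 1 FPKM are called not expressed |
| fold pseudocounts | 0.5 (counts), 0.1 (FPKM) | — | keep zero cells finite; small relative to typical signal |

All of these are arguments of `pipeline_params()` / the individual
functions and are recorded in every run report.

## Design choices where the design was open

* **Coordinates.** Everything internal is 0-based half-open; GTF input is
  converted on read, BED passes through. Abutting intervals do not
  overlap, and peak clustering deliberately keeps abutting peaks in
  separate clusters.
* **"Upstream/downstream".** Nearest-gene assignment works in reference
  coordinates (left/right of the anchor), ignoring gene strand, matching
  common peak-annotation tools. Ties between genes ending at the same
  coordinate go to the lexicographically smaller gene id, for determinism.
* **Promoters.** One TSS per gene (the gene-model 5' end); the promoter
  interval is `[tss - flank, tss + flank + 1)`, symmetric around the TSS
  base itself.
* **Category map.** Three of the seven category ids are anchored by the
  biology (3 = all three sources, 5 = both target-state factors,
  7 = Foxa2 alone, 2 = progenitor-T alone); the remaining ids
  (1 = T-progenitor + Foxa2, 4 = both T contexts, 6 = target-T alone) are
  a package convention, overridable through `default_category_map()`'s
  replacement.
* **The enhancer unit.** One differential region is one enhancer row, even
  when it contains several binding-profile anchors; its flags are the
  union over contained anchors and its representative anchor comes from
  the highest-precedence source (ties: leftmost).
* **Summit ties.** The leftmost maximal coverage bin wins; a zero-coverage
  peak falls back to its midpoint and is flagged low-confidence.
* **Association unit.** Gene–enhancer association tests the single-bp
  anchor for containment in the gene domain, consistent with the
  summit-based intersection upstream.

## The synthetic-data generator

`sim_config()` fixes the study conditions for all simulated data: a
2 x 200 kb toy genome carrying 20 genes, 30 planted enhancers, a mean
depth of 50 fragments per 1 kb window, a 4-fold accessibility gain at
planted enhancers in condition A, a 10% duplicate rate, lognormal fragment
lengths with a 200 bp median (ATAC-scale inserts), and 5 planted specific
genes per condition at 10-fold expression difference with 0.2 lognormal
noise.

The count model deserves a note. Each window carries a latent
accessibility rate shared by the two conditions, drawn from a gamma
distribution whose shape is `1/dispersion`, so that counts across windows
are negative-binomially dispersed — as real accessibility is — while the
two libraries at any one window are conditionally Poisson around the same
rate (condition A's rate multiplied by the accessibility fold at planted
windows). Sharing the rate is what makes the null simulation genuinely
null for a test that conditions on the window total: independent
negative-binomial draws per condition would build extra between-library
variance into every window and mis-calibrate any binomial-type test by
construction, which is a statement about the simulation, not the method.
With `dispersion = 0` the rate is constant and counts are pure Poisson.

Fragments are placed uniformly *within* their window (lengths clipped to
the window), so window counts exactly realise the drawn rates;
PCR duplicates are injected as a fraction of the emitted library.
Deterministic sub-seeds are derived from the master seed per stage, so
every generator is byte-stable under a fixed seed and stages can be rerun
independently.

What the generator deliberately does **not** emulate: sequence content and
Tn5 insertion bias, mappability structure, replicate correlation,
fragment-length periodicity, peak-shape heterogeneity, and trans-chromosome
artefact pairs. Tests passing on this generator therefore demonstrate the
pipeline's logic and statistical calibration, not robustness to those
real-data pathologies.

## Evaluation conventions and problem sizes

The test suite and the acceptance script evaluate, per run:

* *Null calibration*: 5 seeds x 200 non-overlapping 1 kb windows on
  Poisson libraries (fold 1); the fraction of windows with p ≤ 0.05 must
  sit within the 99% binomial band around 0.05.
* *Planted recovery*: 5 seeds x 20 four-fold regions in a 1 Mb genome at
  depth 50/window, detection at q ≤ 0.05 and fold ≥ 2. Recovery and false
  discovery are measured on the gained-accessibility (condition-A-up)
  calls: that is the direction in which regions were planted and the only
  set downstream stages consume. Calls in the opposite direction are a
  different discovery class and are reported separately by the pipeline.
* *Specific genes*: noiseless simulation must be recovered exactly;
  sigma 0.2 at fold 10 to ≥ 95% sensitivity.
* *Oracle equivalence*: interval overlap, promoter subtraction, blacklist
  filtering, anchor containment and closest-gene search are compared with
  quadratic brute-force implementations on 10^3–10^4 random instances.
* *Determinism*: fixture emission and the end-to-end pipeline are
  byte-identical under a fixed seed.

These sizes keep the whole suite under about a minute on one CPU while
leaving each check statistically meaningful.

## Degenerate inputs

Empty peak sets yield an empty enhancer table and a zero-association
report, not an error; an empty window list yields an empty differential
set; a zero-coverage peak summit falls back to the midpoint with a flag;
genes at chromosome ends get only their existing neighbour; a gene alone
on its chromosome has the whole chromosome as its domain. Mate pairs on
different chromosomes and pairs above the insert cap are counted and
dropped, never fatal.

## Limitations

The differential model tests one pooled library per condition against
library-size expectation; it has no replicate dispersion estimate, so
biological variability between replicate libraries is outside its scope
(as it is for the windowed G-test it mirrors). Enhancer-gene assignment is
purely positional; chromatin contacts are not modelled. FPKM here is the
plain count-length-depth normalisation, not a transcript-resolution
estimate. Reported percentages are rounded half-up to one decimal, which
is worth remembering when comparing to sources that truncate.
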