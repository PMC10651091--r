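# ocre — open-chromatin regulatory element discovery

`ocre` is an R package for calling candidate tissue-specific enhancers by
integrating two layers of evidence: **differential chromatin
accessibility** between two cell populations (ATAC-seq fragment data) and
**combinatorial transcription-factor occupancy** (three ChIP-seq peak
sets). It is written for regulatory genomicists who have fragment-level
ATAC data for two conditions, peak calls for the lineage factors of
interest, a gene annotation, and expression tables, and who want a
reproducible, scriptable path from those inputs to an annotated enhancer
table, enhancer–gene associations, and category summaries.

## The method

Accessibility is compared window-by-window. Chromosomes are tiled with
1 kb windows every 100 bp; a window with fragment counts $n_A$, $n_B$ in
libraries of total size $N_A$, $N_B$ forms the 2×2 table
$\{n_A, N_A - n_A;\; n_B, N_B - n_B\}$, tested with the likelihood-ratio
G-test

$$G \;=\; 2\sum_{\text{cells}} O\,\ln\!\frac{O}{E}, \qquad
G \sim \chi^2_{(1)} \text{ under the null},$$

with expectations from the margins and $0\ln 0 \equiv 0$. P-values are
Benjamini–Hochberg adjusted across all windows; windows at $q \le 0.05$
with normalised fold change $\ge 2$ are merged (same direction, gap
< one step) into differential regions, and regions overlapping promoters
(±5 kb of a TSS) are discarded.

The three peak sets — T in a progenitor state, T and Foxa2 in the target
state — are blacklist-filtered, clustered by transitive overlap, and each
cluster is labelled with one of the seven source combinations
(categories 1–7). Cluster summits (precedence: progenitor-T > target-T >
Foxa2) are intersected, at single-bp resolution, with the regions gaining
accessibility in the target condition: regions containing a summit are
the candidate enhancers. Enhancers are assigned target genes positionally
(intergenic: both flanking genes; genic: host gene(s) plus both flanks),
genes specific to a condition (≥ 3-fold FPKM at both of two stages) are
intersected with the enhancers in their neighbourhood domain, and
per-gene category combinations are tabulated UpSet-style.

A synthetic-data generator (`sim_config()` → `emit_fixture()`) produces
complete toy datasets — genome, fragments with planted differential
windows, peak sets with known combinatorial structure, expression tables
with planted specific genes — with full ground-truth bookkeeping, so the
whole pipeline runs and is testable with no external data.

## Worked example

Generate the default toy dataset and run every stage:

```r
library(ocre)

fix <- file.path(tempdir(), "fx")
out <- file.path(tempdir(), "out")
emit_fixture(sim_config(seed = 1), fix)   # writes BED/BEDPE/narrowPeak/TSV inputs
res <- run_pipeline(fix, out, overwrite = TRUE)
print(res)
```

```
ocre pipeline result
  genes                            20
  fragments_a_raw                  25881
  fragments_b_raw                  21766
  fragments_a                      23292
  fragments_b                      19584
  differential_regions             36
  differential_regions_nonpromoter 34
  a_up_regions                     30
  peaks_t_nmp                      17
  peaks_t_notop                    25
  peaks_foxa2                      19
  binding_profiles                 30
  enhancers                        30
  a_specific_genes                 5
  b_specific_genes                 5
  a_specific_with_enhancer         4
  association: 4 of 5 genes (80.0%)
```

Reading the report: of ~26k raw fragment pairs per library, duplicates
and chrY/chrM removal leave ~23k (condition A) and ~20k (condition B)
fragments. The windowed G-test calls 36 differential regions, 34 of which
survive the promoter filter and 30 gain accessibility in condition A —
exactly the 30 planted enhancer windows on this seed. All 30 binding
profiles built from the three peak sets drop their summits into those
regions, giving 30 candidate enhancers whose categories match the planted
ground truth (`truth_enhancers.tsv` in the fixture directory). Of the 5
planted condition-A-specific genes, 4 have at least one enhancer in their
neighbourhood domain (80.0%). `summary(res)` adds the category-fraction
table and the per-gene UpSet combinations; all intermediates
(`differential_regions*.bed`, `enhancers.bed`, `associations.tsv`,
`upset.tsv`, `report.tsv`) are in `out`.

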