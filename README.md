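# budsig

Tumor budding — single tumor cells or small clusters detaching from the
invasion front — marks aggressive head and neck squamous cell carcinoma but
is scored by eye on H&E slides. `budsig` is an R package for deriving a
transcriptional **tumor budding signature (TBS)** from segment-level spatial
transcriptomics and evaluating it on bulk, single-cell and pharmacogenomic
expression data. It is written for computational biologists who have a
segment × probe count matrix (GeoMx-style digital spatial profiling, with
negative-control probes) and want the full downstream analysis as tested,
composable functions.

## What it computes

**QC and normalization.** Per-segment limit of quantification from the
negative probes,

```
LOQ = max(2, NegGeoMean × NegGeoSD²)
```

segment filters (≥ 40,000 reads, ≥ 80% stitched, ≥ 70% aligned, ≥ 50%
saturation, ≤ 1,000 NTC counts), detection filters (segments detecting
< 5% of genes above their LOQ; genes detected in < 10% of segments),
upper-quartile (Q3) normalization, and case-level aggregation.

**Signature derivation.** Paired/unpaired Wilcoxon contrasts of tumor buds
against every other segment type (adjacent stroma, budding bulk and its
stroma, non-budding bulk and its stroma, pooled immune), BH-adjusted at FDR
5% with |fold change| > 1.5; the signature is the strict intersection of
the up-called genes across all six contrasts.

**Scoring and evaluation.** Per-sample score = mean log2 normalized
expression of the signature genes (the 15-gene pEMT program ships as
`pemt_genes`); two-component Gaussian-mixture cutoffs for bimodal
single-cell score distributions; fold-change-of-percentages enrichment
`(n/K)/(k/N)` with Fisher tests over a GMT catalog; differential Spearman
correlation networks between buds and bulk with a permutation null on
Fisher-Z differences (|rho| > 0.8 at FDR 1%, |ΔZ| ≥ 1.4); ROC with DeLong
CIs; Kaplan–Meier/log-rank, Cox models and survival-optimized cutoffs; and
a signature–drug-response screen.

**Synthetic data.** `generate_spatial()`, `generate_single_cell()`,
`generate_bulk_survival()`, `generate_drug_panel()` and
`generate_geneset_catalog()` simulate every input with the statistical
structure the analysis assumes (negative-binomial segment counts over
background negative probes, planted fold effects and gene-pair
correlations, bimodal single-cell states, signature-linked hazards and
drug responses), so the entire pipeline runs and is testable offline.

## Worked example

Simulate the default study design (24 budding + 19 non-budding cases, 300
genes, 28 bud-specific genes planted at fold 2.5), run QC, derive the
signature, and test how well its score separates buds:

```r
library(budsig)

cfg <- spatial_sim_config(
  planted_signature = data.frame(gene = sprintf("g%04d", 1:28), fold = 2.5),
  seed = 1)
sp <- generate_spatial(cfg)
sp
#> segment_counts: 354 segments x 330 probes (30 negative controls)

post <- filter_by_loq(filter_segments(sp)$kept)
post
#> segment_counts: 274 segments x 286 probes (0 negative controls)

norm  <- q3_normalize(post)
cases <- aggregate_case_level(norm, post$meta)
tabs  <- lapply(bud_contrasts(), function(ct) run_contrast(cases, ct))
sig   <- derive_signature(tabs)
sig$up
#> signature_def 'TBS_up' (up): 26 genes

scores <- score_signature(norm, sig$up)
is_bud <- post$meta$segment_type[match(rownames(norm),
                                       post$meta$segment_id)] == "bud"
roc_auc(scores, is_bud)
#> AUC 1.000 (95% CI 1.000-1.000), p = 4.6e-23 (38 pos / 236 neg)
```

QC removed 80 segments (failed sequencing metrics or low detection) and 14
genes below detection; the derived signature recovers 26 of the 28 planted
genes (two sat below the LOQ in most segments, exactly the genes a real
experiment could not see either), and its mean-log2 score separates bud
segments from all 236 other segments perfectly in this simulation.

`run_pipeline(pipeline_config(seed = 1), "out/")` chains all stages —
simulation, QC, contrasts, signature, scoring/ROC, enrichment, differential
correlation, survival and drug evaluation — writing tidy TSVs plus a
`manifest.json` with parameters and MD5 checksums; reruns are
byte-identical.

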