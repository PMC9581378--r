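# liversig

Discovery of candidate circulating biomarkers of NAFLD severity from liver
biopsy RNA-seq, for computational biologists who want the whole funnel —
differential expression, tissue selectivity, secretion evidence, validation,
cohort statistics — as tested, composable R functions rather than a one-off
analysis script.

## The method

Participants are grouped by NAFLD activity score (NAS = steatosis +
lobular inflammation + ballooning): NAS 0–1, NAS 2–3, NAS 4–6. A candidate
biomarker gene must survive three filters:

1. **Differential expression.** Counts are modelled as negative binomial,
   variance μ + αμ², with median-of-ratios size factors and moderated
   method-of-moments dispersions. Each higher-NAS group is contrasted
   against NAS 0–1 by a Wald test on log2(μ_c/μ_r) with the standard error
   from observed Fisher information; genes with Benjamini–Hochberg adjusted
   p < 0.05 in either contrast form the DEG set.
2. **Liver selectivity.** On a gene × tissue TPM atlas, each gene's
   coefficient of variation across tissues (sd/mean; 0 for a flat profile,
   √T for a liver-only profile) is combined with its liver expression:
   selective ⇔ liver TPM ≥ 10, CV above the empirical 90% quantile, and
   liver the maximal tissue.
3. **Secretion.** Membership in any of three evidence lists (hepatocyte
   secretome, blood proteome detection, predicted secreted), or an explicit
   indirect-metabolite mapping for non-secreted enzymes whose circulating
   product is measurable (the MAT1A → S-adenosylmethionine case).

Survivors are ranked by the average of three ranks (padj ↑, |log2FC| ↓,
CV ↓) and re-tested in independent cohorts with BH within the candidate set
and per-gene direction concordance across datasets. A directional Stouffer
gene-set stage (Σz/√n over signed per-gene z-scores) and the cohort's
nonparametric statistics (Kruskal–Wallis, Dunn vs reference, Spearman,
median/IQR tables, frequency-table filters) round out the pipeline. A
seeded synthetic-data generator with planted ground truth stands in for the
unpublished raw study data and makes every stage testable end to end.

## Worked example

```r
library(liversig)

cfg <- sim_config(seed = 7)          # the default synthetic study
val <- list(V1 = simulate_counts(sim_config(seed = 501))$data)
res <- run_discovery(cfg, validation_datasets = val)

res$candidates[, c("gene_id", "log2fc", "padj", "cv", "liver_tpm",
                   "marker_mode", "composite_rank")]
#> # A tibble: 4 × 7
#>   gene_id log2fc     padj    cv liver_tpm marker_mode         composite_rank
#>   <chr>    <dbl>    <dbl> <dbl>     <dbl> <chr>                        <int>
#> 1 G0001    -1.99 2.88e-37  5.39      496. direct                           1
#> 2 G0002    -2.03 7.16e-24  5.35      453. direct                           2
#> 3 G0003    -1.83 1.36e- 7  5.40      508. direct                           3
#> 4 G0004    -1.87 3.04e- 8  5.37      489. indirect_metabolite              4
```

The four rows are exactly the four genes the generator planted as
down-regulated, liver-selective candidates: estimated log2 fold changes near
the planted −2, CVs near the one-hot ceiling √33 ≈ 5.74, and the fourth
gene entering through the indirect-metabolite route rather than a secretion
list. Validation in an independently simulated cohort confirms every sign:

```r
res$validation$concordance
#> # A tibble: 4 × 4
#>   gene_id n_datasets n_concordant direction_concordance
#> 1 G0001            1            1                     1
#> 2 G0002            1            1                     1
#> 3 G0003            1            1                     1
#> 4 G0004            1            1                     1

glance(res$de[["NAS4-6"]])
#> # A tibble: 1 × 6
#>   contrast reference n_genes n_deg  n_up n_down
#> 1 NAS4-6   NAS0-1       2000    37     3    34
```

`autoplot()` methods give the PCA and volcano views;
`plot_selectivity(res$scores, deg_set = unlist(res$degs$sets),
candidates = res$candidates)` draws the CV–versus–liver-TPM plane with the
candidates labelled. `tidy()`/`glance()` work on DE, enrichment and PCA
results. The printed cohort summaries ship as data:
`filter_count(histology_frequencies(), variable == "nash" & grade == "yes")`
returns 5.

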