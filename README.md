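# maitsig

Tools for studying mucosa-associated invariant T (MAIT) cells in paired
single-cell TCR + gene-expression data and in bulk tumor cohorts.

MAIT cells are innate-like T lymphocytes restricted by the monomorphic
antigen-presenting molecule MR1. They are identifiable directly from their
TCR: a semi-invariant α chain using **TRAV1-2 joined to TRAJ33, TRAJ12 or
TRAJ20**. `maitsig` exploits this to build a complete, testable analysis
chain for MAIT biology in cancer:

1. **Repertoire** — classify MAIT cells from contig records
   (`classify_mait()`), build clonotypes under exact α–β pair or
   shared-chain semantics (`build_clonotypes()`), and summarize TRAJ/TRBV
   segment usage (`vj_usage()`).
2. **Clonal structure** — tissue preference as observed/expected ratios
   R<sub>O/E</sub> = O<sub>ij</sub> / (r<sub>i</sub>c<sub>j</sub>/N)
   (`compute_roe()`), clonotype sharing across blood/normal/tumor
   (`summarize_sharing()`), and pre/post-therapy clone dynamics by
   two-sided Fisher exact tests with within-patient BH correction
   (`classify_clone_dynamics()`).
3. **Differential expression** — an empirical-Bayes moderated linear model
   written for this package: per-gene residual variances s²_g with df d
   are shrunk toward a prior s₀² with df d₀ estimated by moment-matching
   log-variances to a scaled F distribution (optionally a lowess trend in
   mean expression), giving posterior variances
   s̃²_g = (d₀s₀² + d·s²_g)/(d₀ + d) and moderated t / F statistics
   (`moderated_fit()`, `hierarchical_deg()`). A hierarchical F-then-pairwise
   procedure screens genes before pairwise contrasts.
4. **Signatures** — per-cell module scores as means of per-gene z-scores
   (`score_module()`; activation, exhaustion and the 11-gene MAIT
   signature ship in `mait_gene_sets()`), and consensus derivation of
   MAIT markers as the strict intersection of per-stratum qualifying sets
   across tissue × cancer strata (`derive_consensus_signature()`).
5. **Pseudo-bulk benchmarking** — sum counts of n randomly drawn cells,
   score the signature, and correlate it with the known MAIT fraction
   after removing ±3-MAD score outliers (`make_pseudobulk()`,
   `evaluate_scores()`).
6. **Bulk prognostics** — Kendall τ_b marker correlation matrices
   (`kendall_matrix()`), rule-based per-cancer signature trimming to a
   fixed point (`trim_signature()`), per-sample MAIT/T scores with
   OLS residualization (`score_bulk()`), tertile-stratified Cox
   proportional-hazards and Kaplan-Meier/log-rank survival tests
   (`survival_test()`), and MR1 association (`mr1_association()`).
7. **Synthetic data** — seeded generators with full ground truth
   (`generate_sc_dataset()`, `generate_bulk_cohort()`) so the entire
   pipeline is exercisable and testable without any external download.

Everything is tidyverse-native: functions take data frames and return
tibbles, results chain with the pipe, fitted objects have `tidy()` /
`glance()` methods, and result types have `plot_*()` / `autoplot()`
visualizations.

## Worked example

```r
library(maitsig)

# a synthetic cohort: 3 patients x (blood, normal, tumor), planted MAIT
# population, clonal structure and marker effects
sim <- generate_sc_dataset(sc_sim_config(seed = 42, patients = 3,
                                         cells_per_tissue = 400))

cls <- classify_mait(sim$contigs, sim$annotations)
table(cls$subset)
#>  CD4  CD8 MAIT Treg
#> 1146 1508  237  709

roe <- compute_roe(sim$annotations)
compare_roe(roe, levels = c("normal", "blood"))
#>   subset group1 group2 mean1 mean2    n1    n2 statistic    df p_value
#> 1 MAIT   normal blood   1.60 0.695     3     3      6.13  3.61 0.00496

sc <- score_module(sim$matrix, mait_gene_sets()$mait_signature)
compare_scores(sc, setNames(sim$annotations$subset == "MAIT",
                            sim$annotations$cell_id))
#>   group1 group2    n1    n2 median1 median2     W   p_value
#> 1 FALSE  TRUE    3363   237  0.0137   0.742  3054 3.22e-144
```

The MAIT cells land where they were planted: enriched in normal tissue
relative to blood (mean R<sub>O/E</sub> 1.60 vs 0.70, Welch p ≈ 0.005),
and their signature score separates cleanly from non-MAIT cells (median
0.74 vs 0.01).

On the bulk side:

```r
bc <- generate_bulk_cohort(bulk_sim_config(seed = 42))   # n = 600, planted
                                                         # log HR 0.5 / SD
tr <- trim_signature(kendall_matrix(bc$cohort))
tr
#> <trimmed_signature> 11/11 genes retained (eligible)

sb <- score_bulk(bc$cohort, tr)
survival_test(sb, bc$cohort, endpoint = "os")
#> <mait_survfit> OS (tertile): HR 1.931 [1.527, 2.443],
#>   Wald p 4.01e-08, log-rank p 2.39e-08
```

With a planted positive hazard link, the high-score tertile shows the
expected excess hazard over the low tertile (HR ≈ 1.9); `autoplot()` on
the result draws the Kaplan-Meier curves, and `tidy()` returns the full
one-row summary.

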