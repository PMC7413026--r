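---
title: "Methods: MAIT cell identification, signatures and prognostics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: MAIT cell identification, signatures and prognostics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`maitsig` analyzes mucosa-associated invariant T (MAIT) cells across
single-cell and bulk transcriptomes. This vignette documents the models
the package implements, the parameters that matter, the synthetic-data
generators used to validate every stage, and the design decisions taken
where more than one reasonable convention exists.

## 1. MAIT cell identification from the TCR

MAIT cells carry a semi-invariant TCR α chain — TRAV1-2 joined to TRAJ33,
TRAJ12 or TRAJ20 — restricted by the MHC-Ib molecule MR1. `classify_mait()`
therefore calls a cell MAIT iff *any* of its productive TRA chains matches
that V–J pattern; all comparisons strip IMGT allele suffixes (`*01`)
because contig annotators differ in allele reporting. A cell is
analysis-eligible only with at least one productive TRA *and* TRB chain;
ineligible cells are flagged and excluded from repertoire statistics
rather than guessed at.

Two clonotype semantics are provided (`build_clonotypes()`):

* **exact_pair** — cells share a clonotype iff their defining (α, β)
  chains agree on V gene, J gene and CDR3 nucleotide sequence. For cells
  with several productive chains per locus, the lexicographically
  smallest (V, J, CDR3-nt) chain is the defining one — a deterministic
  tie-break; the choice only matters for the rare multi-chain cells.
* **shared_chain** — cells merge (transitively) whenever they share at
  least one productive α *and* one productive β CDR3 nucleotide sequence,
  the convention used when re-analyzing droplet datasets where chain
  recovery is patchier. Exact-pair clones always nest inside shared-chain
  clones.

"Clonal" means clonotype size ≥ 2. `vj_usage()` counts each MAIT cell
once — its MAIT-defining α chain contributes the TRAJ segment and its
defining β chain the TRBV segment — so a 30-cell clonotype contributes 30
counts to its bin, matching per-cell frequency readouts.

## 2. Tissue preference and clone dynamics

Tissue preference is quantified per patient as the ratio of observed to
chi-square-expected cell counts, R~O/E~ = O~ij~ / (r~i~ c~j~ / N). Under
proportional margins all ratios are exactly 1; a subset absent from a
tissue gives 0. Patients sampled in a single compartment carry no
information and are dropped with a warning. Cross-patient comparisons use
a two-sided unpaired t-test on per-patient ratios, Welch by default since
nothing guarantees equal variances across tissue groups.

Clone dynamics (`classify_clone_dynamics()`) tests each clonotype's 2×2
table `[[pre, pre_total − pre], [post, post_total − post]]` with a
two-sided Fisher exact test (probability-mass definition, as in standard
implementations), adjusts within patient by Benjamini–Hochberg, and
labels fates: `pre_only` / `post_only` (seen on one side), `expanded` /
`depleted` (q < 0.05 with a proportional increase / decrease), `stable`
otherwise. Patients with fewer than `min_cells = 10` clone-member cells
on either side are skipped — below that, sampling error dominates any
clonal signal. No multiplicity convention is universal for clone-level
tests; within-patient BH was chosen to mirror the gene-level convention
used elsewhere in the package.

## 3. Moderated differential expression

The package implements its own empirical-Bayes moderated linear model for
log2-scale expression. Per gene, a one-way group-means fit yields the
residual variance s²~g~ on d = N − k degrees of freedom. The marginal
distribution of the s²~g~ is modeled as s₀² F(d, d₀); taking logs,

e~g~ = log s²~g~ − ψ(d/2) + log(d/2)

has mean log s₀² − ψ(d₀/2) + log(d₀/2) and variance ψ′(d/2) + ψ′(d₀/2),
so d₀ follows from inverting the trigamma function on the excess spread
of the e~g~ (Newton iteration) and s₀² from the mean. With `trend = TRUE`
the prior mean is a lowess smooth (span 0.5) of e~g~ against mean
expression, so lowly and highly expressed genes get their own prior
scale — appropriate for log-CPM single-cell data, and the default in
`deg_config()`. Posterior variances are the df-weighted compromise
s̃²~g~ = (d₀ s₀² + d s²~g~)/(d₀ + d); moderated t and F statistics use
d₀ + d total degrees of freedom, capped at the pooled residual df of the
dataset (an estimated prior cannot carry more information than the data
that produced it). When the trend explains all dispersion, d₀ → ∞ and
every gene is shrunk fully onto the trend line. Genes with exactly zero
residual variance take the prior variance directly so no statistic
divides by zero; when their means are also equal the t is reported as 0.

The hierarchical procedure (`hierarchical_deg()`) first screens genes
with a moderated F test across all groups at BH-adjusted p < 0.2, then
runs pairwise moderated t-tests on the survivors. The spec of this
procedure leaves the stage-2 adjustment universe open; adjusting within
the survivor set alone would let the stage-1 selection cap error control
at 0.2 rather than 0.05 (the F screen hands stage 2 only extreme genes,
and a small denominator then waves them through). The package therefore
pools all contrast p-values and adjusts with the *full* universe —
genes × contrasts — as denominator, the "global" convention of standard
moderated-statistics software. Under a simulated global null (2,000 genes,
3 × 50 cells) the realized false-discovery rate is then at the nominal
0.05; the degenerate setting `f_prefilter_threshold = 1` reduces exactly
to unfiltered pairwise testing. Significance additionally requires a
linear fold-change of `fc_threshold` (default 1.5; 1.25 is conventional
for checkpoint-therapy contrasts), applied on the log2 scale as
|Δ mean log2| ≥ log2(fc) — i.e. a ratio of geometric means.

`bh_adjust()` is a validated wrapper around the standard step-up
adjustment; the test suite checks it (together with the Fisher, Kendall
and moderated-t routes) against independent brute-force implementations
on thousands of random fixtures.

## 4. Module scores and the consensus MAIT signature

A module score (`score_module()`) is the per-cell mean of per-gene
z-scores of log2-scale expression. z-scoring makes the score invariant to
per-gene affine rescaling; zero-variance genes contribute 0 rather than
NaN. The shipped gene sets are the 11-gene activation/function list, the
8-gene exhaustion list, the 11-gene MAIT signature, pan-T (CD3D/E/G) and
7 NK markers. Group comparisons of scores use the Wilcoxon rank-sum test:
the groups being compared (e.g. tumor vs normal cells) are unpaired, so
the two-sample rank-sum test is the applicable rank test; exact
enumeration is used when both groups have ≤ 25 untied observations, the
tie-corrected normal approximation otherwise.

`derive_consensus_signature()` generalizes the consensus rule: within
each cancer × tissue stratum, a gene qualifies iff it is significantly
*higher* in MAIT cells than each comparator subset present (CD8, CD4,
Treg; BH-adjusted p < 0.1 and fold-change ≥ 1.5 per pairwise moderated
t-test), and the signature is the strict intersection of qualifying sets
across all strata — so adding strata can only shrink it, and genes absent
from a stratum's matrix cannot qualify there. Tissue strata with fewer
than 20 MAIT cells are merged into the same cancer's tumor stratum before
testing; 20 generously covers the kind of sparsely sampled normal-tissue
compartments (n ≈ 15) that motivate merging while leaving adequately
sampled strata independent. A stratum with no MAIT cells at all is an
error — there is nothing to merge.

## 5. Pseudo-bulk validation

`make_pseudobulk()` draws n cells without replacement (independently per
sample, so samples may overlap), sums raw counts, normalizes to
log2(CPM + 1) — counts per million substitute for TPM with UMI data,
where no length correction applies — and scores the signature as the
plain mean of the normalized expression of the signature genes. The
plain mean (not the per-cell z-mean) is deliberate for pseudo-bulk:
z-scoring across simulated samples would couple each sample's score to
the cohort composition; both rules are exposed via `score_method`.
Before scoring, `prefilter_signature()` drops signature genes detected in
under 1% of cells — lowly expressed members contribute only noise at the
bulk level; 1% is the package's operationalization of "low expression"
for droplet data.

`evaluate_scores()` removes samples whose score lies more than 3 raw
median absolute deviations from the median — the MAD is unscaled (no
1.4826 consistency factor) since the rule is a robust fence, not a
normal-theory estimator — then reports Pearson r and two-sided p against
each subset's true fraction. Outliers are determined once, on the MAIT
score, and all subsets' correlations use the surviving samples.

## 6. Bulk cohorts: trimming, scoring, survival

`kendall_matrix()` computes Kendall τ_b (tie-corrected) between all
marker pairs across samples, with two-sided p from the tie-adjusted
normal approximation — rank-based and hence robust to the heavy tails and
ties of log-TPM cohort data. Constant genes get τ = 0 with a flag.

`trim_signature()` keeps only signature genes whose bulk behavior is
consistent with a MAIT/T-cell transcript. "Correlated" means τ > 0 with
p < 0.05 — the validation logic concerns positive co-abundance, and 0.05
is the package-wide default significance level. The three rules
(anchored on SLC4A10, the most MAIT-specific transcript across
datasets): correlation with the anchor; correlation with all, or all but
one, other *retained* genes; correlation with at least two pan-T
markers. Because rule 2 is self-referential, the rules are iterated to a
fixed point: the worst violator (most rules broken; ties broken by the
smallest τ with the anchor) is removed and the rules re-evaluated. This
terminates in at most 11 iterations, is deterministic, and re-running on
the retained set changes nothing. The anchor is exempt from rule 1 only;
in the degenerate case where rules 2–3 eject the anchor itself, rule 1
becomes unsatisfiable and the signature collapses to ineligibility —
which is the honest reading of a cohort whose anchor gene does not behave
like a MAIT transcript. Cancers retaining fewer than 5 of the 11 genes
are ineligible for survival analysis.

`score_bulk()` computes the MAIT score (mean of per-gene z-scores over
samples), the T score (same, from CD3D/E/G), and the residual MAIT
score — the OLS residual of MAIT on T score with intercept — which is
exactly orthogonal to the T score and thus measures MAIT abundance net of
overall T-cell infiltration. `survival_test()` stratifies the score at
the 33rd/67th percentiles (linear-interpolation quantiles; boundary
samples to the lower stratum) and fits a univariate Cox model of high vs
low (middle excluded) with Efron tie handling — the default contrast
because two-group survival comparisons are the standard presentation;
a continuous mode (per-SD hazard) is exposed as an option and is the one
used for parameter-recovery checks, since the generator's hazard link is
continuous. Kaplan–Meier curves and the log-rank test accompany every
fit; a stratum with zero events flags the hazard ratio as unstable
rather than suppressing output.

## 7. What the synthetic generators emulate

`generate_sc_dataset()` mirrors the structure of multi-patient cancer
T-cell atlases: three tissue compartments per patient; MAIT frequencies
per tissue defaulting to 5% (blood), 10% (normal tissue) and 5% (tumor) —
within the ranges reported for blood and mucosal/hepatic tissue; non-MAIT
cells split CD8/CD4/Treg at 45/35/20; MAIT TCRα J usage 0.85/0.10/0.05
for TRAJ33/12/20 (TRAJ33-dominant, as observed repertoires are); clone
sizes geometric with p = 0.6 so most clonotypes are singletons and large
clones naturally span compartments; β chains biased toward TRBV6/TRBV20.
Counts are negative binomial with dispersion 0.3 (droplet-like) or
log-normal with σ = 0.5 (full-length-like). Planted MAIT markers default
to a log2 effect of 2 — MAIT signature genes are near-exclusive in real
data, so a 4-fold elevation is conservative-realistic; validation runs
that specify weaker effects (e.g. log2FC 1.5 for consensus recovery) pass
them explicitly. Stratum-specific decoy markers (elevated in one
cancer–tissue stratum only) exercise the strictness of the consensus
intersection. Planted effects act on expression *rates*; the realized
effect is measured as the log2 ratio of mean counts, since the
log2(CPM + 1) transform compresses differences for lowly expressed genes.

`generate_bulk_cohort()` mixes per-subset expression profiles by
Dirichlet-distributed fractions (tumor/stroma as `other`), multiplied by
a shared log-normal immune-load factor (σ = 0.8) before renormalization —
real cohorts vary widely in lymphocyte infiltration, and that shared
variation is what couples pan-T and MAIT marker abundances; without it,
compositional anti-correlation would make the trimming rules reject
everything, which is a property of unrealistic mixtures rather than of
the method. MAIT markers sit at a moderate bulk background (~4 TPM) and
32-fold higher in the MAIT profile; MR1 is linearly coupled to the MAIT
fraction. Survival times are exponential with hazard
h₀·exp(β·z), z the standardized true MAIT fraction (β = 0.5/SD, h₀ =
1/1500 per day by default); censoring is exponential with its rate solved
numerically (uniroot on the realized hazards) so the marginal censored
fraction hits the configured 30% even at nonzero β.

What the generators do *not* emulate: doublets, ambient RNA, batch
effects, patient-level expression heterogeneity beyond library size,
gene–gene correlation beyond the planted structure, and real marginal
distributions of any particular cohort. Passing tests therefore
demonstrate that the algorithms recover planted truth under clean
conditions — not that any biological conclusion transfers to a specific
real dataset.

## 8. Numerical choices and problem sizes

All randomized operations require an explicit integer seed and restore
the RNG state afterwards; an absent seed is an error, never silent
nondeterminism. QC bounds follow the wording "< 1,200 or > 25,000 UMI":
strict inequalities remove, so boundary cells are kept. Mitochondrial
genes are recognized by the configurable symbol prefix `MT-`. Gene
identity is the case-sensitive symbol string — no alias mapping.

The validation suite uses problem sizes chosen to estimate each property
precisely while keeping a full run in the tens of seconds: oracle
equivalence on ≥ 1,000 random fixtures per statistic; null-FDR estimation
on 200 replicates of 2,000 genes × 150 cells; consensus recovery on
3 cancers × 3 tissues × 200 cells per subset; pseudo-bulk validation on
300 samples of 3,000 cells; Cox coverage on 200 cohorts of n = 600 and
log-rank calibration on 1,000 null cohorts of n = 300.

## 9. Known limitations

* The moderated model is a one-way layout: no covariates, voom-style
  observation weights, duplicate-correlation or random effects.
* Clonotype matching is string-exact on CDR3 nucleotides; no fuzzy
  matching of sequencing errors.
* The trimming rules are the stated ad hoc procedure, not an inferential
  method; their fixed point depends on the chosen α.
* Gene-length-aware TPM is out of scope; CPM substitutes for UMI data.
* Survival modeling is univariate; no clinical covariates or competing
  risks.
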