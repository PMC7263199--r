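---
title: "Methods: cancer-type-specific methylation markers with methylmark"
author: "methylmark authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cancer-type-specific methylation markers with methylmark}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methylmark)
```

## Scope and model

methylmark implements a marker-discovery workflow for Infinium 450K-style
methylation data across multiple tumor cohorts. The quantity of interest at
each CpG is the beta value, the methylated fraction of total probe
intensity,

$$\beta = \frac{M}{M + U + \text{offset}} \in [0, 1],$$

computed by `compute_beta()` with `offset = 0` by default (the plain
ratio; the conventional Illumina offset of 100 is available through the
argument). Downstream, the package identifies CpGs hyper-methylated
specifically in one target cancer cohort, calls a CpG island methylator
phenotype (CIMP) among the target tumors, screens methylation–expression
correlations, and fits progressive logistic diagnostic models.

Every stage consumes three plain containers: a probes × samples beta
matrix, a probe annotation (chromosome, position, CGI relation, gene,
gene feature, SNP flag), and a sample sheet (cohort, tissue class,
pairing id, survival fields). A synthetic-data generator produces all
three with planted ground truth, so the whole pipeline is testable
without any external download.

## Probe exclusion

`filter_probes()` removes, in order: probes on chrX/chrY, SNP-flagged
probes, and — when detection p-values are available — probes with
detection p > 0.01 in *strictly more than half* of all samples (a probe
failing in exactly half is retained; the rule is read literally). The
order sex/SNP-first is a package choice; per-rule exclusion counts are
reported so the attrition is auditable either way.

## Differential methylation

Site-level calls (`call_dmcs()`) compare tumor with adjacent normal
samples, paired (by patient id) or unpaired. The test family is chosen by
a normality decision: a one-sample Kolmogorov–Smirnov test of the
standardised betas against the standard normal (`ks_normality()`, α =
0.05). Because array-scale studies typically make one global decision
after inspecting the genome-wide distribution, the default is a single
global flag (`normal_dist = TRUE` selects the t family); per-CpG decisions
can be made by calling `ks_normality()` per probe and running the two
families on the corresponding subsets. The unpaired t-test is Welch's
(cohort sizes are rarely balanced); the Wilcoxon signed-rank path drops
zero differences and uses exact enumeration up to n = 25, a
continuity-corrected normal approximation beyond.

A CpG is a DMC when |Δβ| > 0.2 and Benjamini–Hochberg FDR < 0.01, with
Δβ = mean(tumor β) − mean(normal β); `hyper` and `hypo` are assigned
symmetrically. Missing betas are deleted pairwise; a pair with either
member missing is dropped in paired tests. Region-level analysis
(`summarize_regions()`, `region_differential()`) averages the non-missing
member CpGs of each (gene, region) — CGI-relative or TSS-relative — per
sample, then applies the paired t-test with the same thresholds; whether a
Δβ threshold belongs at the region level is genuinely open, so the default
mirrors the site level and `delta_min = 0` switches to p-only calls.

Feature enrichment (`feature_enrichment()`) builds the 2 × 2 table of a
probe set vs a reference set against membership of a genomic feature, and
reports the two-sided Fisher exact p together with the *sample* odds ratio
(ad)/(bc) and a Woolf log-OR interval. The sample OR is used deliberately
— published enrichment ORs in this literature are sample ORs, not the
conditional-MLE OR that `fisher.test()` estimates. Both reference choices
are supported: hyper vs hypo, and hyper vs all retained CpGs. Zero cells
yield an infinite OR with an uninformative interval and a degenerate flag.

## CIMP identification

`select_variable_cpgs()` keeps CpGs with tumor standard deviation > 0.2
and normal mean < 0.05 — unmethylated in normal tissue, variably
methylated across tumors. The sd reading of the threshold is intentional:
a standard *error* over hundreds of samples could never exceed 0.2, so the
rule is only meaningful as a standard deviation.

The cluster number is chosen by Monti-style consensus clustering
(`consensus_cluster()`): repeated 80% subsampling, inner K-means, and a
consensus matrix per candidate k; the chosen k minimises the PAC score
(fraction of pairwise consensus values inside (0.1, 0.9)), ties breaking
to the smallest k. PAC is this package's declared criterion; consensus
procedures differ across tools and none is canonical. The final partition
comes from `kmeans_cluster()` — Euclidean K-means on samples, best of
`n_init = 20` random initialisations by within-cluster sum of squares
(random restarts rather than k-means++ seeding; with 20 restarts on
array-scale separations the difference is immaterial, and the restart
scheme is what the selection rule is defined over). The cluster with the
highest mean beta over the selected CpGs is the CIMP cluster
(`call_cimp()`), exact ties to the lowest index with a warning.

Survival is compared by Kaplan–Meier estimates and the multi-group
log-rank test (`km_logrank()`, χ² with groups − 1 df), with overall
survival in days and right censoring.

## Expression screens

The package's DE caller (`call_degs()`) is a deliberately simple
stand-in: log2(CPM + 1), Welch t per gene, BH FDR, thresholds |log2 FC| >
1 and FDR < 0.01. It is *not* a negative-binomial GLM; studies wanting a
count-model DE step can import any external table with columns
(gene, log2_fc, p_value, fdr) via `as_deg_table()` — the rest of the
pipeline is agnostic to how the table was produced.

Correlation screens use Pearson r between a CpG's beta and a gene's log2
CPM (the transform is a package choice; raw counts make r scale-dependent),
with p from the t-distribution on n − 2 df and α = 0.05. *Cis* pairs are
each DMC with its own annotated gene; *trans* pairs are all DMC × DEG
combinations excluding the cis pairs (the exclusion is implied rather than
stated in most workflows; it is explicit here). `bias_summary()`
stratifies the Neg/Pos/NS fractions by DMC direction crossed with DEG
direction (trans) or gene feature (cis).

One calibration subtlety: under a permutation null obtained by shuffling
the expression columns *once*, all pairs share the same shuffle, and
because both matrices carry tumor/normal bimodality the per-shuffle
significant-call rate is extremely variable (a lucky shuffle partially
re-aligns the groups for every pair at once). The package's tests and the
acceptance script therefore average the rate over 30 independent
permutations, which estimates the marginal type-I rate; it sits slightly
below 5% because the bimodal marginals make the t-based p mildly
conservative.

## The specificity cascade

`cascade_filter()` screens hyper-CpGs for target-cohort specificity in
four stages, all using the same Δβ > 0.2 / FDR < 0.01 rule (no separate
threshold is defined for the cross-cancer comparisons; reusing the one
stated rule is the least surprising choice):

1. paired hyper-DMC in the target cohort;
2. unpaired hyper-DMC in the target cohort;
3. hyper vs healthy tissue (unpaired — no pairing exists);
4. hyper vs the tumors **and** the normals of every background cohort.

BH correction is applied within each comparison over the candidate set of
that stage. All stage-4 comparisons are evaluated on the fixed
post-stage-3 candidate set; this makes the result independent of the
order in which background cohorts are processed and makes the cascade
monotone (adding a background cohort can only shrink the final set). The
comparisons are direct two-sample tests of target tumors against the
other cohort's samples (an alternative reading — requiring the *other*
cohort's own Δβ to be small — is not implemented). A background cohort
with fewer than 3 samples in a class is skipped with a warning and the
panel is marked partial. All stage flags of surviving probes are retained
for audit; flags after the first failure are `NA`.

`rank_by_fdr()` orders DMCs by FDR (ties: larger |Δβ|, then probe id) for
the top-200 hierarchical-clustering display, and
`hierarchical_separation()` scores tumor/normal separation as the
adjusted Rand index between the 2-cut of an average-linkage dendrogram
and the labels.

## Diagnostic modelling

Features are ranked by information gain (`information_gain()`):
equal-frequency 10-bin quantile discretisation, IG in bits. The binning is
a declared choice (no discretisation is canonical); it is recorded with
the model. The classifier is a ridge-penalised logistic regression fitted
by IRLS (`fit_logistic()`), minimising the average negative
log-likelihood plus λ/2‖coef‖² with λ = 1e-4 and an unpenalised
intercept. The penalty exists for a concrete reason: marker CpGs are
selected for Δβ > 0.2 and are frequently completely separating, where the
unpenalised MLE diverges; the small ridge guarantees a finite optimum
while changing non-separated fits negligibly. Per-observation scaling
makes the fit invariant to duplicating the data. Convergence is declared
at a max coefficient change below 1e-8 (cap 100 iterations;
non-convergence is an error carrying the last iterate).

`progressive_evaluation()` refits on the top-k ranked markers for k =
1..k_max and reports the test AUC per k — the cost-effectiveness curve
over panel size. AUC uses the Mann–Whitney concordance identity with 0.5
credit for ties (`roc_auc()`). `cross_cohort_misclassification()` applies
the model to every (cohort, tissue) group at the 0.5 decision threshold
(no threshold-selection procedure is modelled) and reports the percentage
called target — the specificity screen against other cancers and normal
tissues. Test-set betas are used as-is; cross-platform harmonisation is
out of scope.

## The synthetic generator

`sim_config()` fixes the study conditions; the defaults are the
conditions under which the package's whole-pipeline properties are
verified:

| parameter | default | meaning |
|---|---|---|
| `n_probes` | 20 000 | CpGs simulated |
| `cohorts` | target 50/50 + 4 × (40 tumor / 20 normal) | desk-scale stand-in for a multi-cancer design |
| `n_markers`, `marker_delta` | 8, 0.4 | target-specific hyper-CpGs and their β shift |
| `background_hyper_frac`, `background_hyper_delta` | 0.02, 0.3 | pan-cancer hyper probes (shift in *every* cohort's tumors) |
| `beta_dispersion` | 50 | Beta-noise concentration κ |
| `n_cimp_extra` | 200 | bimodal high-variance CpGs completing the CIMP block |
| `cimp_fraction`, `cimp_delta` | 0.2, 0.3 | CIMP subcluster size and extra shift |
| `survival_hr`, `censor_rate` | 3, 0.3 | CIMP hazard ratio; censoring fraction |
| `expr_coupling` | −2 | log2-expression slope per unit β for coupled pairs |
| `snp_frac`, `sex_frac` | 0.05, 0.03 | annotation fractions exercising the filters |

Noise is `Beta(μκ, (1−μ)κ)` — bounded, variance-shrinking near 0 and 1,
the standard behaviour of beta values. Baselines are a bimodal mixture
(mostly-unmethylated and mostly-methylated modes) mimicking the familiar
two-peak array histogram. Paired samples share a patient-id string;
pairing is exact-id matching.

The CIMP block needs one non-obvious design decision. A subcluster formed
*only* by adding `cimp_delta = 0.3` to 20% of tumors caps the tumor-wide
standard deviation at 0.3·√(0.2·0.8) ≈ 0.12, which the sd > 0.2 selection
rule can never find. The block therefore consists of the markers plus
`n_cimp_extra` CpGs that are bimodal (≈0.05 / 0.60, coin-flip per tumor)
in **every** cohort's tumors — giving them sd ≈ 0.28 so selection finds
them, and making them pan-cancer so the cascade's stage-4 comparisons
correctly reject them. CIMP samples gain `cimp_delta` on top of the block.
The planted cluster number is consequently 2 (CIMP vs rest); the
consensus-clustering recovery checks target that k.

Survival is exponential proportional hazards (baseline 1/1095 per day)
with censoring implemented as: with probability `censor_rate`, the
observation is cut uniformly before its event time. Expression is
negative binomial (size 20) on a log2 baseline in [4, 10], with planted
DE genes shifted ±2 log2 units in tumors and coupled probe–gene pairs
receiving `expr_coupling · β` on the log2 mean — cis pairs couple each
marker to its own annotated gene, trans pairs couple markers to distinct
down-regulated DE genes.

What the generator does *not* emulate — and hence what passing tests do
not demonstrate about real data: Infinium type-I/II probe chemistry and
dye bias, batch effects, cell-type composition, spatial correlation of
neighbouring CpGs, realistic LD between SNP probes, and the skewed,
heavy-tailed dispersion structure of real RNA-seq. Recovery results on
synthetic data bound what the algorithms can do under their own
assumptions; they are not estimates of sensitivity on TCGA-scale data.

## Numerical and degenerate-input choices

- Row-wise t statistics are computed vectorised; constant-difference rows
  get p = 1 (zero shift) or p = 0 (non-zero shift) rather than NaN.
- Probes with fewer than 3 usable observations are reported `ns` with
  reason `insufficient_obs` and excluded from the BH family.
- `compute_beta()` returns missing on a zero denominator.
- Correlations with a constant margin are `NS` with a degenerate flag.
- Consensus PAC ignores sample pairs never co-subsampled; the chosen-k tie
  break is the smallest k.
- K-means with k equal to the sample count returns the identity partition.
- All simulation seeds derive from one master seed via a fixed affine map
  below 2³¹, so every artifact is reproducible from a single integer.

## Problem sizes used in the checks

The packaged property checks run the marker-recovery experiment at the
default conditions (20 000 probes, 20 seeds), DMC null calibration at
5 000 probes × 50/50 samples, CIMP recovery at 3 000 probes × 100 tumors,
survival calibration over 200 replicates of 100 + 100 samples, diagnostic
evaluation with a 400-sample training and 1 000-sample testing cohort, and
correlation screens over ≥ 2 000 pairs × 30 permutations. These sizes are
the package's declared verification conditions: large enough that sampling
error is far below every asserted margin, small enough to run routinely.

## Known limitations

- The DE stand-in ignores count overdispersion structure beyond a fixed
  NB size; externally computed DE tables are first-class inputs instead.
- Consensus clustering is one concrete procedure among several in use;
  PAC-based k selection can prefer k = 2 on weakly nested structure.
- The cascade tests every background comparison at the same thresholds;
  no multiplicity control is applied *across* stages.
- Cross-platform beta harmonisation, cell-composition adjustment and
  genomic-adjacency DMR detection are out of scope.
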