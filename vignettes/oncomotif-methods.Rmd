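---
title: "Methods: from pooled miRNA screen to oncomotif signature"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from pooled miRNA screen to oncomotif signature}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oncomotif)
```

## Overview

`oncomotif` implements an inference chain for identifying
proliferation-promoting microRNA seed families and tracing their downstream
footprint through multi-omic target evidence and tumor cohorts. The chain
has five analysis stages — pooled-screen enrichment/depletion statistics,
seed-motif discovery, multi-evidence target integration, cohort signature
derivation with survival analysis, and miRNA–mRNA correlation profiling —
plus a first-class synthetic-data module that generates every input with
planted ground truth, so the whole chain can be validated end to end by
parameter recovery.

This vignette explains the statistical model behind each stage, the
parameters that matter and their defaults, what the generators emulate (and
do not), and the design choices made where the design was genuinely open.

## Screen analysis

A pooled overexpression screen transduces a library of miRNA expression
vectors (miR-Vecs) into a cell population, then compares clone abundances
across conditions by sequencing the recovered inserts. Here the three
conditions are a baseline (`Ctrl0`), 30 days of normal culture (`Ctrl30`)
and 30 days under an EGFR tyrosine-kinase inhibitor (`Gef30`), each in
biological triplicate. Enrichment between `Ctrl0` and `Ctrl30` indicates
increased proliferation; depletion between `Ctrl30` and `Gef30` indicates
drug sensitization.

The statistics are deliberately simple and match screening practice:

* **Normalization.** Each library is scaled to total reads
  (reads per million, `normalize_counts()`). Column sums are exactly 1e6.
* **Read filter.** A vector is analyzed only if it was sequenced at least
  300 times in *every* replicate of at least *one* condition
  (`filter_min_reads()`). The filter operates on raw counts: being
  "sequenced at least 300 times" is a property of reads, not of normalized
  abundance.
* **Testing.** Per vector and contrast, replicate values
  $x_r = \log_2(\mathrm{RPM}_r + 0.5)$ are compared with a two-sided
  two-sample t-test; the log2 ratio is the difference of group means.
  Welch's unequal-variance form is the default (pooled-variance Student
  available by flag): triplicate groups with unequal variances are the norm
  in screen data. The pseudocount 0.5 keeps zero counts finite and treats
  enrichment and depletion symmetrically. When both groups have zero
  variance the analytic limit applies — p = 1 for equal means, p = 0
  otherwise — and the row is flagged so users can exclude such degenerate
  cases.
* **Calling.** Volcano cutoffs: enriched if log2 ratio ≥ 1.5 and p < 0.05,
  depleted if ≤ −1.5 and p < 0.05. Fold thresholds are inclusive and the p
  threshold strict, matching the usual phrasing of such cutoffs. No
  multiple-testing correction is applied at this stage — the screen is a
  hypothesis generator, and hits are validated downstream.

Two phenotype summary helpers accompany the screen:
`proliferation_index()` computes (S + G2/M) / G0/G1 from cell-cycle phase
fractions, and `delta_delta_cq()` implements relative qPCR quantification
(per-replicate ΔCq against a reference small RNA, then ratio-normalization
of the mean ΔCq to a non-targeting control).

## Seed motifs

The seed is defined here as 5' nucleotides 1–8 of the mature miRNA — the
region that base-pairs with mRNA 3'UTRs. This differs from the common 2–7
or 2–8 conventions; `extract_seed()` exposes the alternative region for
comparability with other tools, but 1–8 is the default because it is the
definition under which the shared AAGUGC hexamer was identified.
`find_shared_motifs()` enumerates every k-mer (default k = 6, supported
4–8) occurring in any hit's seed and counts containing seeds among hits and
across the whole library; at k = 8 this degenerates to exact-seed grouping.
`motif_enrichment()` adds a quantification layer beyond the qualitative
shared-motif observation: an upper-tail hypergeometric test of motif
counts among hits against the library background.
`assign_seed_family()` collects all catalogue miRNAs whose seed contains a
motif — the "seed family" whose members are expected to share a target
spectrum. DNA-alphabet FASTA input is accepted and silently coerced (T→U),
since miRNA catalogues circulate in both alphabets.

## Target integration

miRNAs repress targets by mRNA degradation and translational inhibition,
so target evidence is collected at both the mRNA and the protein level:
per-gene log2 abundances for mimic-transfected vs control triplicates,
compared with the same t-test machinery as the screen
(`differential_table()`). Genes are stratified by prediction consensus —
the number of algorithms (0–9) nominating the gene as a target — into the
bins "0", "1–2", "3–4", ">4" (`stratify_by_predictions()`). The empirical
distribution of the consensus count is typically bimodal with a mode at
five algorithms, which motivates the five-algorithm cutoff for calling.

`ecdf_shift()` quantifies what is usually shown visually: the cumulative
fold-change distribution of each stratum against the no-prediction
reference, with a two-sample Kolmogorov–Smirnov test (asymptotic p-values)
as the shift statistic. A genuine targeting signal appears as a left shift
of the high-consensus stratum only.

`call_putative_targets()` implements the final rule: a gene is a putative
target iff it is significantly downregulated (log2 fold change < 0 and
p < 0.05) at the mRNA *and/or* protein level, *and* is predicted by at
least five algorithms. Genes absent from the protein layer are evaluable
via the mRNA branch only; missingness is recorded, never imputed. The
`evidence` field records which branch fired, and the call is monotone in
both thresholds.

## Cohort signature and survival

At cohort level the family members' expression is summed per sample
(`sum_family_expression()`), because seed-sharing miRNAs act on a common
target spectrum and individual members dominate in different tumors.
Wherever a symmetric scale is needed (correlations, ordering) the
transform log2(sum + 1) is used; the raw reads-per-million scale remains
available by argument, since the choice is not canonical.

The signature pipeline is:

1. **Percentile groups** (`percentile_groups()`): the top and bottom
   pct = 5% of tumors by summed family expression, with group size
   k = ⌈n·pct/100⌉ and ties broken by sample id for determinism.
2. **Differential signature** (`derive_signature()`): per-gene Welch t-test
   of high vs low on log2 expression, Benjamini–Hochberg FDR over all
   tested genes, selection at FDR < 1e-5 and |log2 fold change| > 1.
3. **Clustering** (`hierarchical_cluster()`): samples are clustered on the
   signature genes with complete linkage on 1 − Spearman correlation, and
   the two main clusters are the k = 2 cut. Genes are mean-centered across
   samples before computing sample–sample correlations (the heat-map
   convention). This is a deliberate design choice: without centering, the
   shared per-gene baseline dominates every pairwise correlation, the
   correlation matrix is nearly uniform, and the k = 2 complete-linkage cut
   degenerates into an unstable split at an arbitrary point of the activity
   continuum; centering recovers the two main expression groups. The
   raw-scale rank distance remains available (`center_genes = FALSE`), in
   which case cluster labels are invariant under strictly increasing
   per-sample transforms.
4. **Genotype association** (`genotype_association()`): two-sided Wilcoxon
   rank-sum test of summed expression between genotype groups (e.g.
   TP53-mutant vs wild type); exact enumeration for combined n ≤ 20 without
   ties, otherwise the tie-corrected normal approximation.
5. **Survival** (`km_logrank()`, `cox_regression()`): Kaplan–Meier
   product-limit curves per cluster with a log-rank test, and Cox
   proportional-hazards regression (Efron tie handling by default, Breslow
   by flag; Wald p-values) with cluster membership, mutation status and
   copy-number status modeled as categorical covariates. The 5% level is
   used for survival significance throughout. Display truncation of KM
   curves is a plotting matter and never affects the test.

## Correlation networks

Because part of miRNA action is mRNA degradation, targets that matter in
tumors should anti-correlate with family expression across a cohort.
`correlate_genes()` computes the per-gene Pearson correlation with
log2(sum + 1); zero-variance genes get an undefined (NA) correlation,
never r = 0. `call_inverse_targets()` applies the strict cutoff
r < −0.15 to a candidate set (typically the putative targets from the
omics stage). `rank_cancers_by_ts_correlation()` orders cancer types by
the mean correlation over a curated tumor-suppressor panel — the
seven-gene panel TGFBR2, CDKN1A, LATS2, RBL2, ZBTB7A, PTEN, RB1 is the
package default. `export_network()` produces a correlation-colored node
table from a curated node/edge file; edges are copied from curation, never
inferred — this module is a correlation profiler, not a structure learner.

## Synthetic data: what it emulates

Every generator is a pure function of its config (seed included), returns
planted truth labels, and writes the same formats the analysis reads.

**Screen** (`generate_screen()`): baseline clone abundances are log-normal
(sdlog 1 — clone representation in pooled libraries spans orders of
magnitude); per condition, relative abundances are renormalized (a pooled
screen measures composition, so an enriched clone dilutes everything else)
and counts are negative-binomial with variance μ + φμ² (φ = 0.05 by
default; real pooled screens rarely publish their dispersion, and the
default is chosen as a realistic mid-range overdispersion). Planted
enriched clones gain 2^2.5 in relative abundance between `Ctrl0` and
`Ctrl30`; planted depleted clones lose 2^2.5 between `Ctrl30` and `Gef30`;
a configurable subset (default 8 of 15/15) carries both phenotypes,
mirroring the dual proliferation/sensitization hits that motivate the
motif analysis. Hits are planted among clones with expected baseline
coverage of at least `plant_floor` (600 reads, twice the read filter):
recovery experiments measure statistical recovery, not the censoring of
clones too shallow ever to be callable. Planted hit miRNAs carry the
configured motif (default AAGUGC) within seed positions 1–8; background
seeds are motif-free by rejection sampling, which guarantees motif
specificity of the planted truth.

**Omics** (`generate_omics()`): per-gene replicate values are Normal
around a gene baseline with noise sd 0.3 (log2 units — a typical replicate
sd for well-powered transcriptome/proteome triplicates); planted targets
(500 of 12 000) are shifted by −1 log2 in the mimic arm at both layers;
the protein layer covers a random 70% of genes; prediction counts are
Binomial(9, 0.7) for targets and Binomial(9, 0.1) otherwise.

**Cohort** (`generate_cohort()`): one latent per-sample activity couples
everything downstream — family miRNA expression (log-linear, slope 0.7,
then rescaled to reads per million), tumor-suppressor repression (−0.8
log2 per activity unit), cell-cycle induction (+0.8), TP53-mutation
probability (logistic, slope 1), and relapse hazard (exponential, log-rate
slope 0.8, 30% uniform censoring). Tumor activity is standard Normal;
normal samples sit at −2 with residual spread 0.5. The tighter normal
spread is deliberate: normal tissue does not span the tumor activity
continuum, and a unit spread would place ~2% of normals above the tumor
median — making the expectation that all normals co-cluster with
low-activity tumors unattainable regardless of clustering quality. Family
members span a decreasing baseline (one member dominating, as seen for
real seed families); 300 uncoupled background miRNAs make the
reads-per-million normalization non-trivial.

**What the generators do not emulate.** Read-level sequencing artifacts,
isoform structure, copy-number segments, batch effects, non-Gaussian
expression heavy tails, correlated gene modules beyond the single latent
factor, and informative censoring. Passing recovery tests therefore shows
that the chain's statistics are correctly implemented and powered under a
faithful-but-idealized model — not that the pipeline is robust to every
pathology of real cohort data.

## Numerical choices and degenerate inputs

* t-tests: Welch–Satterthwaite df; both-groups-zero-variance rows take the
  analytic limit (p ∈ {0, 1}) and are flagged.
* BH adjustment: step-up q = min over j ≥ i of m·p(j)/j, clipped at 1
  (via `p.adjust`).
* Hypergeometric, KS, Wilcoxon, Kaplan–Meier, log-rank and Cox statistics
  are delegated to `stats` and `survival`; the test suite checks each
  against independent brute-force oracles (pmf summation, jump-point
  maximization, full enumeration of rank assignments, hand product-limit,
  manual complete-linkage agglomeration) at 1e-10 relative tolerance.
* Ties: percentile groups and motif tables break ties by id/lexicographic
  order for determinism; `hclust` merge ties resolve by index order.
* Degenerate inputs are errors with named offenders: zero-total sequencing
  libraries, constant sample profiles under rank correlation, constant Cox
  covariates, empty hit sets, empty effective families.

## Problem sizes

The recovery suites run at the documented default conditions: 20 simulated
screens of 450 vectors × 9 libraries; 10 omics experiments of 12 000 genes;
10 cohorts of 400 tumors + 20 normals; and a 1 000-sample two-group
exponential simulation for Cox recovery. The full test suite completes in
well under a minute on a single CPU; `scripts/acceptance.R` recomputes the
headline quantities in a few seconds.

## Known limitations

* The screen's dispersion and abundance spread are modeling choices; real
  screens with heavier clone dropout will push more vectors below the read
  filter and reduce recovery.
* The cohort model has a single latent factor; real tumor cohorts carry
  subtype structure that can split the two main clusters differently.
* The KS quantification of ECDF shifts and the hypergeometric motif
  enrichment are quantification layers added on top of analyses that are
  usually reported qualitatively; both are labelled as such in the
  documentation.
* `run_pipeline()` discovers the shared motif from its own screen hits but
  derives the cohort signature from the cohort's generated family — the
  two simulated universes (screen catalogue, cohort miRNA panel) are
  intentionally distinct.
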