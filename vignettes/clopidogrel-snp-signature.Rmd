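---
title: "Discovering SNP signatures of clopidogrel resistance: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering SNP signatures of clopidogrel resistance: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clopisig)
library(dplyr)
```

## The problem

Clopidogrel, a P2Y12-receptor antagonist, shows strongly heterogeneous
efficacy: a substantial fraction of patients — more than half of diabetic
peripheral-artery-disease (PAD) patients in East-Asian cohorts — retain high
on-treatment platelet reactivity ("clopidogrel resistance"), conventionally
defined as more than 234 P2Y12 reaction units (PRU) on the VerifyNow assay.
Known CYP2C19 loss-of-function star alleles explain only part of this
variability, which motivates an agnostic, array-wide search for SNPs that
separate resistant from non-resistant patients.

`clopisig` implements that search as a reusable, fully testable pipeline:

1. **QC** — remove monomorphic SNPs (minor allele frequency 0) and SNPs with
   a missing-call rate above 10%.
2. **Association filter** — per-SNP allelic chi-square with odds ratio;
   keep SNPs with p < 0.05 and OR > 10.
3. **Consensus ranking** — 100 stratified 80/20 re-splits; on each training
   set a random forest, a linear SVM and a LASSO each nominate their top-20
   SNPs; SNPs are ranked by how many of the 300 (iteration x learner) top
   sets contain them.
4. **Signature evaluation** — sweep the number of top-ranked SNPs through
   four classifiers (random forest, SVM, decision tree, gradient boosting),
   measuring validation AUC and accuracy, and select the smallest signature
   whose AUC is within a tolerance of the best observed.
5. **Genotype-frequency comparison** — per-SNP 2 x 3 (group x genotype)
   chi-square between resistant and non-resistant patients.
6. **Network** — connect the signature genes through one-hop bridge
   proteins in a local protein-interaction edge list.

Because the original cohort's genotype data are not publicly deposited, the
package ships a synthetic cohort generator with planted risk alleles; every
pipeline stage is exercised and validated against it.

## The synthetic cohort generator

`simulate_cohort()` emulates the discovery design: `n_cases` diabetic PAD
patients and `n_controls` age/sex-matched community controls (defaults
64/64, the genotyped cohort size), genotyped at `n_snps` biallelic SNPs.

* **Null SNPs.** A control-arm allele frequency `p` is drawn uniformly from
  `maf_range` (default 0.05–0.5) and used in both arms. Genotypes are
  Hardy–Weinberg: each subject's call is Binomial(2, p), independent across
  SNPs. The study's real MAF spectrum is unpublished; the uniform spectrum
  is a declared simplification, not an inference.
* **Planted SNPs.** `n_causal` SNPs (default 3) receive a case-arm
  frequency from the allelic-odds-ratio inversion
  `q = OR p / (1 - p + OR p)` with `OR = causal_or` (default 15, the
  strong-effect regime the filter is designed to catch).
* **Missingness.** Each call is independently missing with probability
  `missing_rate` (default 0.02, typical array scale).
* **Phenotype.** Cases draw PRU from Normal(300, 50), controls from
  Normal(160, 50), clipped at 0; the resistance label is always recomputed
  as PRU > 234, never stored independently. Real community controls are not
  on clopidogrel and would have no PRU at all; giving them the sensitive
  component keeps the table complete and is a documented simplification.
* **Determinism.** One integer seed drives a fixed draw order (null
  frequencies, causal SNP selection, genotype calls, missingness mask, PRU,
  group labels, covariates), so an identical spec reproduces byte-identical
  output across sessions and releases.

The generator deliberately omits linkage disequilibrium, population
stratification and age/sex confounding. Passing tests on this cohort
therefore demonstrate that the pipeline recovers strong, independent allelic
effects under clean sampling — not that it is robust to LD leakage or
stratification artifacts in real array data.

Planted effects are defined between the case and control *arms*, so the
generator-backed tests and the default pipeline configuration use the
`case_control` label contrast. On real data the published filter contrasts
resistant vs non-resistant patients, which is `snp_association()`'s default
(`contrast = "resistance"`); both are available everywhere.

## Stage-by-stage statistical choices

### QC (`filter_snps`)

MAF is computed over non-missing calls with both arms pooled (standard
array QC; the source protocol does not state per-arm computation). Both
rules are strict inequalities taken literally: MAF exactly 0 removes, and a
missing rate *greater than* 0.10 removes, so 10 missing in 100 subjects is
retained. Removal reasons are assigned with MAF-0 priority so the report is
deterministic; an all-missing SNP has no defined MAF and is removed under
the missingness rule with a warning. Filtering is idempotent and invariant
to column order.

### Association (`snp_association`)

The test is **allelic**: each SNP's 2 x 2 table counts alternate vs
reference alleles (2 per subject) in each arm, missing calls excluded
pairwise. An allelic table is what yields the single odds ratio per SNP
that the filter needs; the genotypic 2 x 3 comparison is provided separately
(`genotype_frequency_test()`) for the signature SNPs. The statistic is the
uncorrected Pearson chi-square in closed form,

```
chi2 = N (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d)),   p = P(Chi2_1 >= chi2),
```

and the odds ratio is `ad/bc` with the Haldane–Anscombe correction (0.5
added to all cells when any cell is 0), so infinity is never returned. A
zero margin flags the record untestable rather than raising an error.

**No multiple-testing correction is applied.** The published filter uses raw
p < 0.05 jointly with OR > 10; this package reproduces that procedure
faithfully rather than improving it. At array scale the p-threshold alone
would pass tens of thousands of null SNPs — it is the OR > 10 requirement
and the downstream consensus ranking that provide the real selectivity.
The methods text of the source protocol says "OR > 1" while its results
apply OR > 10; the default follows the results (`or_threshold = 10`) and
`or_threshold = 1` is one argument away.

### Consensus ranking (`consensus_rank`)

"100-time bootstrapping of random combinations of patients" is interpreted
as repeated stratified random 80/20 re-splitting without replacement
(`replace = TRUE` gives a classical within-class bootstrap with out-of-bag
validation, behind a flag). Training quotas per class follow the
largest-remainder rule, so a 100-subject balanced cohort always splits
exactly 80/20.

Learner settings are declared package choices — the source names no
hyperparameters:

| learner | importance score | settings |
|---|---|---|
| `forest` | impurity (Gini) importance | `ranger`, 500 trees, single thread |
| `svm` | absolute weight of linear fit | `e1071`, cost 1, standardized genotypes |
| `lasso` | absolute coefficient at CV-selected penalty | `glmnet`, binomial, 5-fold CV, 40-value path to `lambda.min.ratio = 0.05` |

Missing genotypes are mode-imputed per SNP before fitting (learners need
complete matrices; ties go to the smaller genotype so imputation is
deterministic). Genotypes are standardized for the SVM and LASSO only; the
forest sees raw additive codes. Zero LASSO coefficients and constant
features score 0 and therefore rank last; all ties break by ascending SNP
id, making every ranking — and the final consensus — exactly reproducible
from the seed. Counts conserve: the sum over SNPs equals
`n_iterations x |methods| x top_k`.

`top_k = 20` per learner per iteration matches the size of the signature
pool ultimately reported from this design (a top-20 consensus list).

### Evaluation and selection (`evaluate_curve`, `select_signature`)

For each feature count `k` and each of the four evaluation models, the
model is fit on the training 80% using the `k` highest-consensus SNPs and
scored on the held-out 20%; AUC and accuracy are averaged over 20 splits
(the source does not say whether its curve is one split or an average;
averaging is the lower-variance choice). AUC is the normalized
Mann–Whitney rank statistic with midranks, which equals trapezoidal ROC
integration exactly; accuracy thresholds the predicted probability at 0.5
(for the SVM, a logistic link on the decision margin, so the 0.5 threshold
coincides with the margin sign). The four models default to
forest/SVM/tree/XGBoost (50 boosting rounds); the alternative list with
LASSO in place of XGBoost is available via `models =`.

"Minimum needed feature number" is undefined in the source; it is
formalized as the smallest `k` whose best-model AUC is within `tolerance`
(default 0.005) of the global maximum over all (model, k) pairs, with ties
broken by fewer features and then model name order — deterministic given a
curve. Because training and validation folds are drawn from one finite
cohort, null SNPs whose sampled genotypes happen to correlate with the
labels cohort-wide can lift validation AUC by a few thousandths; with a
0.005 tolerance the selected size therefore occasionally exceeds the
planted count on unlucky simulation seeds. That is a property of
resampling-based evaluation at n of a few hundred, not of the selection
rule.

The published reduction from the top-20 pool to the "top eight annotated
SNPs" is implemented as an annotation filter (`annotation =`) that removes
unannotated SNPs from the ranking before the sweep; beyond annotation
status no further reduction criterion is stated in the source, so none is
invented.

### Clinical statistics (`fisher_exact`, `mann_whitney`, `sample_size_two_proportions`)

* **Fisher's exact test** enumerates the hypergeometric support and sums
  point probabilities no greater than the observed one (relative tie
  tolerance 1e-7) — the two-sided convention under which the trial's
  printed baseline-medication p-values (0.034 aspirin, 0.036 DPP4)
  reproduce exactly. Zero-margin tables return p = 1 with a warning.
* **Mann–Whitney U** uses midranks; with 12 or fewer total observations and
  no ties the p-value is exact by enumeration, otherwise a normal
  approximation with tie and continuity corrections (matching
  `wilcox.test(correct = TRUE)`).
* **Sample size** uses the pooled-variance normal approximation with
  *nearest-integer* rounding: 70% vs 30% at alpha 0.05 / power 0.80 gives
  23.31, printed as 23 per group (the common ceiling convention would give
  24 — the discrepancy is deliberate and documented). Attrition inflates
  the evaluable total as `floor(n_total / (1 - loss))`: 46 evaluable at 15%
  loss gives 54 enrolled.

Survival analyses (Kaplan–Meier, log-rank, Cox) are deliberately out of
scope: they are off-the-shelf fits with no recomputable inputs here.

### Network (`build_subnetwork`)

The subnetwork contains the signature genes plus every **bridge** protein
lying on a path of length at most 2 between two distinct signature genes
(single intermediates, matching the displayed topology of such networks;
no formal inclusion rule is published, so this reconstruction is the
package's declared choice and `max_path_length` is exposed). Edges are the
induced subgraph; signature genes absent from the edge list are kept as
isolated nodes with a warning. Matching is case-insensitive after resolving
aliases (`LRBA1` → `LRBA` by default). Output is invariant to edge-list row
order and edge orientation, and monotone in `max_path_length`. The packaged
edge list is synthetic illustrative plumbing (see
`inst/extdata/README.md`); real analyses should supply a local BioGRID TAB
export.

## Problem sizes used by the test suite

The suite validates statistical behaviour at sizes where the asymptotics it
relies on are standardly valid, chosen once:

* null calibration of the 0.05-level allelic test: 500 subjects/arm, 2,000
  null SNPs (MAF 0.1–0.5), expecting the significant fraction within 3
  binomial standard errors of 0.05;
* planted-signal recovery: 3 causal SNPs at OR 15, 200 subjects/arm, 300
  candidate SNPs, 100 bootstrap iterations, 20 independent seeds, requiring
  all 3 planted SNPs in the consensus top-10 in at least 19 runs;
* odds-ratio convergence: 5,000 subjects/arm, planted OR recovered within
  10%;
* Fisher's exact test: exhaustive agreement (to 1e-12) with a
  binomial-coefficient enumeration oracle over every 2 x 2 table with total
  at most 40.

## Known limitations

* No LD, stratification or confounding in the generator — see above.
* The raw-p + OR filter inherits the multiplicity behaviour of the original
  procedure; it is a screening heuristic, not an error-controlled test.
* The consensus counts have no null distribution attached; they order SNPs
  but are not p-values.
* With `case_control` contrasts on genotyped case/control arms, the
  signature discriminates case status; resistance-specific signal requires
  PRU-labelled patients and the `resistance` contrast.
* The bridge rule reconstructs a displayed network style; different
  evidence filters over a real interaction database will change the bridge
  set.
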