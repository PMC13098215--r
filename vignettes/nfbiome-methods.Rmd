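---
title: "Classifying infectious and non-infectious neutropenic fever from gut microbiome and metabolite profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying infectious and non-infectious neutropenic fever from gut microbiome and metabolite profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Neutropenic fever (NF) in patients undergoing induction chemotherapy for
acute myeloid leukemia is treated empirically with broad-spectrum
antibiotics, although in most episodes no infectious source is ever
confirmed. Distinguishing *infectious* NF (a positive culture or defined
infection) from *non-infectious* NF (fever with no isolate, typically driven
by sterile mucosal injury) from stool-derived data is therefore a question
of real clinical consequence: gut microbial communities and their
fermentation products — short-chain fatty acids (SCFAs) such as butyrate,
propionate and pentanoate — are mechanistically tied to epithelial barrier
integrity and systemic inflammation.

`nfbiome` implements, as a tested and reusable pipeline, a workflow for this
three-group setting (infectious NF / non-infectious NF / no fever):
compositional preprocessing, ecological diversity statistics, univariate
screening, an *aggregate* gradient-boosted-tree classifier with
importance-based biomarker selection and SHAP interpretation, and a
biomarker-centered Spearman co-occurrence network. Because the matched
metabolite and clinical tables of real cohorts are generally not public, the
package ships a synthetic cohort generator with planted ground truth, so
every stage is testable end to end.

## The synthetic cohort generator

`generate_cohort()` draws a three-group cohort whose default shape
(45/15/14) matches a fever-onset cohort of realistic size and imbalance.

**Taxa.** Genus-level counts are Dirichlet–multinomial. The mean profile is
a fixed Zipf rank–abundance curve (proportion of taxon $j$ proportional to
$1/j$), which matches the steeply skewed rank–abundance shape of gut genus
tables. Making the base profile deterministic rather than re-drawing it per
seed is deliberate: a planted effect on a named taxon then has a
seed-independent realized strength, so simulation studies measure the
method, not the luck of the abundance draw. Group effects multiply the mean
by $e^{\text{shift}}$ before renormalization. Per sample, structural zeros
are imposed by masking each taxon with probability `sparsity` (default
0.25) before renormalizing the Dirichlet mean — microbiome tables are
zero-inflated, and the min/2 pseudocount rule below presumes zeros exist. The
Dirichlet concentration is `dispersion` (default 50, giving the strong
between-sample overdispersion typical of stool profiles), and counts are
multinomial at `sequencing_depth` reads (default $10^4$), returned as
relative abundance (rows sum to 1 exactly).

**Metabolites.** The ten-analyte targeted panel (2-HG, acetic acid,
butyrate, glyceric acid, ketoleucine, lactate, malate, pentanoic acid,
propionic acid, succinate) is modeled log-normally — strictly positive and
right-skewed, matching ion-chromatography–mass-spectrometry abundance
behavior — with per-group log-mean shifts and log-scale noise `met_sigma`
(default 1).

**Clinical covariates.** Categorical variables with 2–4 levels; a planted
association tilts the last level's log-odds per group.

One global seed drives independent per-block substreams, so adding
metabolites does not perturb the taxon draws and identical configurations
are bit-identical. Deliberately *not* emulated: read-level sequencing error
and chimeras, batch effects, and longitudinal within-patient correlation.
Real paired designs share patients between baseline and onset time points;
we decided not to emulate that overlap — each generated cohort is one time
point, and cross-time-point analyses of real data should treat shared
patients explicitly. Consequently, passing simulation studies demonstrates
statistical correctness of the machinery on data with this structure, not
robustness to batch confounding or repeated-measures dependence.

## Preprocessing

* **Prevalence/abundance filter.** Taxa present in fewer than 10% of
  samples or below 0.1% abundance are removed. The removal rule is strictly
  "below", so a feature exactly at a threshold is kept. "Abundance" is the
  per-feature *mean* relative abundance by default (`abundance_stat =
  "max"` is available); the filter applies to taxa only by default, since
  a relative-abundance cutoff has no natural meaning for metabolite
  concentrations.
* **CLR transform.** Zeros are replaced by half the smallest non-zero value
  of the *entire* taxon block (one dataset-wide pseudocount, not per sample
  or per feature), then each row is mapped to
  $\log(x_i / \text{gm}(x))$. Output rows sum to zero and the transform is
  invariant to per-sample rescaling; both are tested to $10^{-9}$.
* **Collinearity pruning.** A greedy scan in column order drops the later
  member of any pair with Pearson $r > 0.9$. Signed $r$ is the default (the
  rule as usually stated); `absolute = TRUE` treats strong negative
  collinearity the same way, since it is equally degenerate for tree
  ensembles. Zero-variance features have undefined correlation; they are
  treated as $r = 0$, never pruned for collinearity, and logged. The
  column-order tie-break is deterministic and documented, so runs are
  reproducible.

Comparisons against thresholds (the $\ge 0.3$ importance rule, the
$|\rho| \ge 0.6$ edge rule, the $r > 0.9$ prune rule) carry a $10^{-12}$
roundoff guard so a value equal to the threshold up to floating-point error
behaves according to the stated inclusive/strict semantics.

## Diversity and univariate statistics

Shannon diversity uses the natural log by default (base is configurable).
Group comparisons use Kruskal–Wallis with the standard tie correction;
Dunn's post hoc $z$ uses pooled tie-corrected rank variance, and pairwise
p-values are reported both unadjusted and BH-adjusted (the default display
is unadjusted with the adjusted values alongside, matching common practice
in exploratory microbiome work).

Bray–Curtis dissimilarity comes from `vegan`; weighted and unweighted
UniFrac are phylogeny-aware distances computed via `phyloseq` behind
`community_distances()`, which validates that the tree is rooted and that
every taxon is a tip. PERMANOVA uses Anderson's pseudo-F via
`vegan::adonis2` with
$p = (1 + \#\{F_\text{perm} \ge F_\text{obs}\}) / (1 + n_\text{perm})$;
`exact = TRUE` enumerates every distinct permutation, which the tests
compare against an independent brute-force oracle. Nuisance covariates such
as batch or sequencing center are handled by restricting permutations to
within-stratum exchanges (`strata`), the standard permutation-based
covariate adjustment when the adjustment method is otherwise unspecified.
Pairwise post hoc PERMANOVA is BH-corrected. Principal-coordinate
ordination truncates negative eigenvalues at zero and reports how many were
truncated.

The Mann–Whitney test uses the exact Wilcoxon distribution when both groups
have at most 8 observations and no ties, and a tie-corrected,
continuity-corrected normal approximation otherwise; two identical constant
samples return $p = 1$ with a warning. χ² is Pearson's without continuity
correction — that convention reproduces published 2×3 exposure tables to
three decimals, which is how the default was fixed. Screening routes
features by class: categorical → χ² (Fisher's exact when the table is 2×2
and any expected count is below 5, the standard small-sample rule), numeric
→ Mann–Whitney; features with $p < 0.3$ (strict) are retained. Screening is
performed on the two NF classes, matching the binary outcome of the models,
and screens all feature classes uniformly.

Heavily zero-inflated taxa make rank tests conservative (discreteness at
zero), so null retention sits slightly below the nominal 30% for very
sparse features; the calibration tests therefore use cohorts with enough
continuous features to measure the nominal level cleanly, and this behavior
is worth remembering when interpreting screens of very sparse taxa.

## The aggregate classifier

Four variable-selection variants are compared: **A** all raw variables,
**B** CLR-transformed taxa, **C** univariate screening at $P < 0.3$,
**D** CLR of the screen-retained taxa (screen first, then transform the
retained columns). The learner is an XGBoost tree booster with binary
objective; clinical covariates enter as 0/1 indicator columns.

One *split* = an 80/20 train/test split stratified by outcome; fivefold CV
with 10 repeats on the training portion chooses the boosting-round count
(we take the median best iteration across early-stopped repeats, an
early-stopping surrogate for "what the CV selected"), the booster is refit
on the full training portion, and AUROC and average precision are measured
on the held-out 20%. The *aggregate* repeats this on 100 independent
stratified splits and pools: mean AUROC, SD, variance, and a 95% CI
half-width fixed as $1.96\,\mathrm{SD}/\sqrt{n_\text{splits}}$. Published
CI/SD pairs for this design are not mutually consistent under any single
formula, so the package fixes one convention, documents it, and tests the
arithmetic exactly. Class imbalance is handled by stratification only; a
class-weight option exists but defaults off.

Per-split feature importance is gain-based, rescaled so the split's top
feature scores 1, then averaged across splits with 0 contributed where a
feature went unused. A max-normalized scale is the one under which a fixed
$\ge 0.3$ selection threshold plausibly yields the handful of biomarkers
such workflows report; sum-normalized gain shares would make 0.3 nearly
unreachable. Biomarkers are the features with mean importance $\ge 0.3$
(inclusive), intended to seed a reduced "final" aggregate model run on
fresh seeds.

Two structural defaults matter here. First, `colsample_bynode` (per-node
feature subsampling, the decorrelation device of random forests) is fixed
at 0.3 and is *not* one of the seven tuned parameters: taxa and
the metabolites they produce are strongly redundant, and without per-node
subsampling, gain collapses onto whichever member of a redundant group a
tree happens to try first, making aggregate importance unstable and
selection erratic. Second, the default `model_config()` (60-round cap,
depth 3, eta 0.3, subsample 0.8, colsample_bytree 0.5) is sized for
cohorts of tens of samples.

A caveat the null simulations make explicit: on a *null* cohort the
top-ranked noise feature's max-normalized mean importance frequently
exceeds 0.3, because with heavily overlapping 80% training sets the same
spuriously correlated feature keeps winning splits. Importance-based
selection is therefore only meaningful jointly with the aggregate AUROC — a
model near 0.5 has no biomarkers regardless of its importance ranking.

Hyperparameters are tuned coarse-to-fine: up to 500 uniform random draws
from bounded ranges per round, scored by stratified fivefold CV AUROC on
identical folds; each parameter's range then shrinks to the span of the top
decile, stopping when all ranges shrink by less than 10% or after three
rounds, followed by a small grid (≤ 3 points per parameter) on the final
space. Default bounds: eta [0.01, 0.3], max_depth [2, 8], min_child_weight
[1, 10], subsample and colsample_bytree [0.5, 1], gamma [0, 5], nrounds
[50, 500]. The returned configuration is the argmax over everything
evaluated, with the full trace.

SHAP values come from the booster's native TreeSHAP (`predcontrib`); they
are additive per sample (tested to $10^{-6}$ against the margin
prediction), features are ranked by mean |SHAP|, and a direction summary
(sign of the correlation between feature values and SHAP values) states
whether high values push toward the infectious class.

## The biomarker network

Spearman correlations are computed on *raw* (untransformed) values for
every feature pair, with categorical clinical covariates as 0/1 indicators
per level (the encoding is otherwise unspecified; indicators are the least
committal choice). Pairs with $|\rho| \ge 0.6$ (inclusive) are candidate
edges with sign retained; constant features are excluded and logged. The
two-level extraction keeps *primary* edges (incident to a biomarker) and
*secondary* edges (incident to a direct neighbor of a biomarker) — an edge
survives iff an endpoint lies in the biomarker set or its one-hop
neighborhood — which the tests verify against a brute-force set
construction.

Metric conventions replicate the reporting of the common graph
visualization tool: average degree is $E/N$ (single-count; every published
value of this quantity we checked matches $E/N$ and none match $2E/N$),
density is $2E/(N(N-1))$, average clustering is the mean of local
clustering with degree < 2 nodes contributing 0, and modularity is the
quality of a seeded, unweighted Louvain partition at resolution 1.
Clustering and modularity depend on the realized partition/graph and are
validated structurally (exhaustive-partition oracle on small graphs), not
against published values. Export is GraphML (round-trippable) or GEXF 1.2
for Gephi.

## Problem sizes used in the validation studies

The shipped studies use sizes chosen to make Monte-Carlo error small while
keeping the suite quick to run: biomarker recovery uses 20 replicate
cohorts of 30 + 30 NF samples (plus 10 no-fever), 40 taxa, the 10-analyte
panel and 4 clinical covariates, with five planted biomarkers (three
mid-rank taxa, two metabolites) at log-scale shift 1.5, each cohort
analyzed by the model-D aggregate at 100 splits; null calibration uses a
550-feature null cohort of 100 + 100 samples for screening level, 100
aggregate splits for chance-level AUROC, and 150 replicates × 99
permutations for PERMANOVA type-I error. Medians over replicate cohorts
are reported throughout because single-cohort importance rankings have
visible Monte-Carlo noise near the 0.3 threshold.

## Known limitations

* The generator plants *independent* group shifts; it does not emulate
  correlated biomarker modules, batch effects, or compositional spillover
  beyond the closure constraint itself.
* Rank tests are conservative for features that are mostly zero.
* Max-normalized importance is interpretable only relative to a split's
  winner; selections from near-chance models are noise (see above).
* UniFrac requires a rooted tree covering all taxa; no midpoint-rooting or
  tip-pruning fallback is applied silently.
* Differential abundance here is the screening-oriented Mann–Whitney +
  fold-change stage; bias-corrected compositional regression frameworks are
  out of scope.
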