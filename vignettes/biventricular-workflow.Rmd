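---
title: "Methods: ventricle-contrast analysis of two-batch omics cohorts"
author: "bivomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ventricle-contrast analysis of two-batch omics cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of the statistics it implements:
the model and its assumptions, the parameters that matter, what the
synthetic cohort generator does and does not emulate, the numerical choices
that were genuinely open, and the limitations we know about. The numbers
quoted are all computed by the test suite or `scripts/acceptance.R`; nothing
here is asserted beyond what those runs check.

## The data and the model

The pipeline targets cohorts of human myocardium in which each heart
contributes a left-ventricular (LV) and sometimes a right-ventricular (RV)
biopsy, samples were quantified in two mass-spectrometry batches years
apart, and a subset of subject–ventricle profiles was re-measured in both
batches. Log2 abundances are modelled as

$$Y = X\beta + W\alpha + \varepsilon,$$

with $Y$ samples × features, $X\beta$ the biology (ventricle, sex,
$\log_2$ age, subject), $W\alpha$ a low-rank unwanted component (batch,
drift) and $\varepsilon$ technical noise. Two assumptions drive everything:

* **Negative controls** — low-variance, fully observed features — carry no
  biological signal, so their variation identifies directions of $W$.
* **Technical replicates** — the same ventricle of the same heart measured
  in both batches — agree biologically, so within-replicate-group contrasts
  contain only unwanted variation and noise.

## RUV-III with missing values

Standard RUV-III residualises $Y_0 = (I - M(M'M)^{-1}M')Y$ over the
replicate incidence $M$, takes the top-$k$ left singular vectors $U$ of the
control block, sets $\hat\alpha = U'Y$ and
$\hat W = Y_c \hat\alpha_c'(\hat\alpha_c\hat\alpha_c')^{-1}$, and subtracts
$\hat W\hat\alpha$. Proteomics data are incomplete, so the package
generalises each step:

* The residual operator becomes a **generalised averaging operator**: for
  each feature, a cell's replicate-group mean is taken over the group
  members *observed for that feature*; a cell whose group has no other
  observed member gets residual 0. On complete data this is exactly the
  projection above.
* Loadings are **available-case least-squares projections**
  $\hat\alpha_j = (U_O'U_O)^{-1}U_O' y^0_j$, where $O$ keeps the samples
  that are observed for feature $j$ *and* belong to a group with at least
  two observed members. Two details matter and were found the hard way:
  using raw rather than residualised values leaks the ~20-log2-unit feature
  means into $\hat\alpha$ whenever observation is partial, and feeding the
  residual-0 convention of broken groups into the fit shrinks loadings
  toward zero. Both are avoided; on complete data both reductions are
  no-ops (asserted at 1e-8 against an independently coded textbook
  implementation).
* Missing cells are never imputed: the normalised matrix has exactly the
  input's missingness mask.

A per-feature complete-cases variant (re-estimating the factor basis on each
feature's observed samples, as RUV-III-C does) is available via
`mode = "complete"` for comparison; it discards the information in
partially observed rows and is considerably slower.

### Choosing k

`k = "auto"` selects the number of unwanted factors by **parallel
analysis**: singular values of the control residual matrix are compared
with the largest singular value across 19 column-permuted copies (fixed
internal stream, so runs are reproducible), and every component above that
null envelope is kept. We first implemented the maximal estimable value,
samples minus replicate groups, as the default; on cohorts with planted
effects it was catastrophic — corrections built from dozens of
noise-estimated loadings on partially observed features injected
location-correlated error, driving the realised false-discovery proportion
above 0.8. The scree of real merged batches is steep, parallel analysis
finds the dominant structure, and an explicitly requested integer `k` is
still honoured (with hard errors when it exceeds the estimable rank).

### Selecting negative controls

The selection rule is "sample variance strictly below the median, and (for
proteomics) no missing values in either batch". The open question is which
matrix the variance is computed on. `variance_scope = "merged"` uses the
merged matrix; but when batch shifts dominate (the regime that makes
RUV-III necessary at all), merged variance is essentially the squared batch
loading, so the rule selects features with *small batch effects*, not
biologically invariant ones — and features with genuine LV−RV effects slip
in. In simulations with planted effects this contaminates the control set
(~10 of ~180 controls), $\hat W$ picks up a ventricle-correlated component,
and the bias $-\hat\alpha_j\,\Delta\gamma$ spreads into every feature: the
realised FDP at BH 0.05 averaged ~0.34 despite perfect recall.
`variance_scope = "per_batch"` computes variances within each batch (where
the batch shift contributes nothing) and requires below-median in both; in
the same simulations it admits zero planted features and restores FDP to
~0.05. The pipeline therefore defaults to `per_batch`; the merged rule
remains available, and the leakage mechanism above is worth knowing about
when interpreting any analysis of this kind.

## Differential expression

Per condition scope (Donor, DCM, ICM, or DCM+ICM pooled as heart failure)
the design is intercept + location (LV = 1) + sex (M = 1) + $\log_2$ age;
sex contrasts use per-location sex effects adjusted for $\log_2$ age.
Paired LV/RV and replicate samples from one heart are correlated, so each
feature is fitted by generalised least squares under
$\Sigma = I + \rho\,B$ ($B$ = same-subject indicator). The consensus $\rho$
is the inverse-Fisher-z 15%-trimmed mean of per-feature REML estimates
(profile likelihood over $\rho \in (-0.95, 0.99)$); on complete data it
matches `limma::duplicateCorrelation` to two decimals in the tests.
Variances are moderated by the scaled-F empirical-Bayes model with
moment-based prior estimation (`limma::fitFDist`); the moderated t and its
p-value are computed by the package's own formula, with the total degrees
of freedom capped at the pooled residual df exactly as in the published
implementation, and agree with `limma::eBayes` to 1e-10. Features whose
observed design is rank deficient, or with fewer than 3 observed samples in
a compared level, are flagged and skipped. BH adjustment is applied over
the tested features.

Two calibration facts from the null simulations are worth stating. With a
homogeneous block correlation, ignoring $\rho$ *inflates* type-I error for
between-subject contrasts (sex within a ventricle) but is *conservative*
for the within-subject LV/RV contrast — blocking helps power there rather
than protecting size. And when the per-feature correlation is heterogeneous
(some features have no subject-level variation), any single consensus value
is a compromise; the LV/RV contrast stays calibrated (raw p < 0.05 fraction
0.035–0.065 in the acceptance run) but between-subject contrasts are more
sensitive to the compromise.

## Enrichment and networks

Over-representation uses the one-sided hypergeometric tail
$P(X \ge x)$ with the **detected post-filter features as universe** —
all-annotated-gene universes import detection bias. Up- and down-regulated
DE sets (BH ≤ 0.05 by default) are tested separately. The mean-rank set
test is a Wilcoxon rank-sum of the set's statistics against the rest:
tie-corrected normal approximation with continuity correction, exact subset
enumeration when both groups have ≤ 10 members (null p-values pass a KS
uniformity check over 1000 simulations at α = 0.01).

Networks take the top-N DE proteins by adjusted p (ties broken by raw p,
then feature ID), N capped at the number of significant features — the
study convention behind N = 200 for donor/ICM and N = 4 for DCM. Pearson
correlations are pairwise-complete over the condition's pooled LV+RV
samples with a minimum overlap of 5; edges carry weight $|r|$ and distance
$1/|r|$; $r = 0$ or under-supported pairs get no edge rather than an
infinite distance. Structural clusters are connected components of
MST ∩ kNN with the union-direction convention (an edge survives if either
endpoint lists the other) and `k = max(1, floor(ln n))`; recursion into
components is off by default. A caution from the tests: at `k = 1` the
1-NN graph cannot contain enough MST edges and the intersection fragments,
so very small k undersegments into many components; the auto choice
recovers two planted 12-node modules in 40/40 seeded runs. Communities come
from `igraph::cluster_walktrap` (walk length 4) on the MST-kNN edge set
with $|r|$ weights (a flag clusters the full correlation graph instead),
and clusters of ≥ 3 nodes are annotated by a competitive mean-rank test on
a membership score refined by correlation to the cluster medoid; a plain
hypergeometric fallback exists. MDS coordinates use the pairwise
top-500-difference RMS distance and classical scaling, with the first
sample's first coordinate forced non-negative for reproducibility.

## The synthetic cohort generator

`cohort_spec()` defaults *are* the study conditions: merged sample counts
27 LV / 13 RV (Donor), 13/5 (DCM), 19/11 (ICM); 40% of subject–ventricle
profiles replicated across the 2018/2020 batches; 2000 features with 10%
planted LV−RV effects of magnitude $|\log_2\mathrm{FC}| \sim U(0.5, 2)$ and
random sign (the effect-size distribution is a placeholder — no empirical
estimate exists for it); per-subject random intercepts (sd 0.3), sex
effects on 20% of features (sd 0.3), $\log_2$-age slopes (sd 0.05); one
latent batch factor with per-feature loading sd 2 on ±1 batch scores
(merged acquisitions from different instruments and years realistically
differ by several log2 units per protein), optional extra drift factors;
residual sd 0.15 (~11% technical CV); ages uniform 30–70, sexes
alternating. Missingness is censoring-like: dropout probability is a
logistic function of the (negated, standardised) true intensity with slope
4, rescaled to an overall 13.4% rate; `mnar_weight` mixes in a
missing-completely-at-random component (default 1, pure censoring). The
slope/weight pair was calibrated once so that a realistic fraction (~18%)
of bright features stays fully observed — the regime in which the
complete + low-variance control rule is even applicable — and not
revisited.

What the generator does **not** emulate: peptide-level roll-up and protein
inference, pooled-QC drift in metabolite peak areas, correlated biology
between features (planted effects are feature-independent), non-Gaussian
heavy tails, and condition-specific effect structure (the same planted
effects apply in every condition). Passing tests therefore demonstrate the
statistics behave as designed under the stated model, not that real
myocardium data meet these assumptions.

## Numerical choices and degenerate inputs

* SVD sign convention: the largest-magnitude element of each score column
  is forced positive.
* Exactly zero control residuals (perfect replicate agreement) short-circuit
  to an identity normalisation instead of a degenerate SVD.
* A singular control loading Gram matrix raises an error suggesting a
  smaller k.
* Re-running the normalisation re-estimates a new basis and will always
  find the next noise directions; the meaningful idempotence — with
  loadings frozen, the re-derived correction is exactly zero — is the
  property the tests assert.
* REML profile evaluations that produce non-finite criteria return a large
  penalty rather than propagating Inf into `optimize()`.
* BH ties are handled by `stats::p.adjust`'s stable ordering; top-N ties by
  raw p then lexicographic feature ID.

## Problem sizes used by the tests

The acceptance checks run 40 seeded two-batch cohorts at 2000 features for
batch-effect removal, 25 planted cohorts at the study arm sizes for FDR and
recall, 3 null cohorts (≥ 2000 feature-tests) for calibration, 1000
simulations for set-test uniformity, and two full pipeline runs at 800
features for byte-level determinism; unit tests use smaller fixtures. These
sizes were chosen to make the Monte-Carlo bounds tight enough to be
meaningful while keeping a full suite run in a few minutes.

## Known limitations

* Under missingness-not-at-random, available-case loading estimates are
  mildly biased for features whose observation probability correlates with
  the unwanted factors; the simulations show ~95% replicate-disagreement
  reduction rather than the complete-data ~99%.
* The consensus correlation compromises across heterogeneous per-feature
  block correlations (see above).
* Merged-variance control selection can leak planted signal under dominant
  batch effects; the per-batch default mitigates but any variance-based
  rule can admit features with small real effects.
* Walktrap on the sparse MST-kNN edge set can split large modules into
  several communities (modularity-driven); the full-graph flag trades that
  for slower, denser clustering.
* Hand-curated metabolite-to-cluster links in network figures are an
  annotation input, not a computation, and are out of scope.
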