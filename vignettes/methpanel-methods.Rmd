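---
title: "Models and methods behind methpanel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind methpanel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(methpanel)
```

`methpanel` implements a three-phase serum cfDNA methylation biomarker
pipeline — pooled-array discovery, candidate prioritization, and targeted
validation — together with a synthetic-data generator that emulates the
study design end to end. This vignette records the statistical models,
the tunable parameters and their defaults, the numerical choices, and the
limits of what the synthetic experiments can show.

## Study design and cohort machinery

Subjects are labelled by their most advanced colorectal finding; the
binary response is **NN** (no colorectal findings, benign pathology,
non-advanced adenomas) versus **AN** (advanced adenomas or CRC). The
default generator composition reproduces the published three-cohort
layout: discovery n = 280 (130 NN / 150 AN), evaluation n = 48
(21 NN / 27 AN) and validation n = 105 (39 NN, 23 distal AA, 19 proximal
AA, 24 CRC). Ages are drawn uniformly on the screening inclusion window
[50, 75] years; sexes alternate within each (cohort, pathological group)
stratum so every stratum of even size splits exactly 50/50.

`stratified_split()` uses proportional allocation with largest-remainder
rounding within strata. The rounding rule is a design choice: the source
design states the realized split sizes but not how fractional seats were
resolved, and largest-remainder is the standard choice that guarantees
exact totals with at most one subject of per-stratum discrepancy.

`build_pools()` builds 10-member pools of 5 men + 5 women from a single
pathological group. Within (group, sex), subjects are sorted by age (ties
broken on subject id, which makes pooling invariant to input row order)
and dealt to the group's pools in snake order. We deliberately chose
snake dealing over nearest-age blocking: blocking minimizes *within*-pool
age spread but thereby maximizes *between*-pool age differences, which
contradicts the design requirement — verified downstream by
`check_pool_age_balance()`, a classical one-way ANOVA of member age on
pool — that pool mean ages show no systematic difference. Snake dealing
gives each pool a comparable age spread and near-equal means.
`assign_to_slides()` deals pools to array slides so no slide carries two
pools of one pathological group, using as many slides as the larger of
the capacity bound and the largest group multiplicity.

## Discovery: moderated differential methylation

Methylation is analyzed on the beta scale (fraction methylated, in
[0, 1]); the effect of interest is Δβ, the AN-minus-NN difference of
means. Modelling betas directly rather than M-values is a deliberate
simplification: effects are reported on the beta scale throughout the
field, pooled betas are far from the boundaries where beta-scale
heteroscedasticity bites, and the residual-normality screen removes
probes where the linear model is inadequate.

Per probe, `fit_probe_models()` fits the two-group least-squares contrast
(equivalent to ordinary least squares with a class indicator; with
independent pools there is no correlation structure to generalize over).
`qc_filter_probes()` first drops probes with any flagged-missing value
("failed positions") and probes whose residuals fail a Shapiro–Wilk
screen at `shapiro_alpha = 0.01` — the screen level is a package choice;
0.01 keeps the type-I loss of probes near 1% while catching heavy-tailed
probes with high probability (both properties are tested).

`ebayes_moderate()` shrinks residual variances with the canonical
empirical-Bayes hierarchy: residual variances are modelled as scaled
inverse-χ² draws with prior degrees of freedom d₀ and prior variance
s₀². The hyperparameters are estimated by moment matching on log s²:
E[log s²] = log σ² + ψ(d/2) − log(d/2) and the excess spread of log s²
over its sampling noise trigamma(d/2) equals trigamma(d₀/2), inverted by
a Newton iteration on the trigamma function (relative tolerance 1e-10,
with asymptotic starts for extreme arguments). The posterior variance is
(d₀s₀² + ds²)/(d₀ + d) and the moderated t is referred to a t
distribution on d + d₀ degrees of freedom. When the observed spread does
not exceed the sampling noise, d₀ is infinite and all probes share s₀².
The implementation is checked in the test suite against an independent
reference implementation of the same hierarchy to 1e-9, and its prior
recovery against generating values. Degenerate input (all s² = 0) is an
error rather than a silent fallback.

Multiplicity is controlled by Benjamini–Hochberg at `fdr = 0.10` (the
discovery threshold of the source design); `bh_adjust()` wraps the
standard step-up implementation and is property-tested against an
explicit min-over-tail oracle. Enrichment of called DMPs in CpG-island
and genic-feature categories uses the one-sided Fisher exact test
(hypergeometric upper tail), split by direction, against the background
of probes that survived QC — the analysis background, not the full
manifest, because categories lost at QC cannot be called; the background
is an argument, so the manifest-wide convention is also available.
No cross-category multiplicity correction is applied, mirroring the
per-category convention of the source design.

## Prioritization: SES and cross-validated ranking

`ses_select()` performs constraint-based forward–backward selection with
statistically-equivalent-signature enumeration. Association is the
likelihood-ratio χ²(1) test between nested logistic models. A feature is
eliminated as soon as some conditioning subset (size ≤ `max_k = 3`) of
the selected set renders it independent of the class at
`alpha = 0.05`; the strongest surviving feature joins the selected set.
Equivalents of a selected feature f are features g that are themselves
significant given the rest of the signature and whose substitution for f
changes the model deviance by less than the χ²(1) critical value at
alpha — a symmetric criterion (the absolute deviance difference does not
depend on which feature is called the reference), so equivalence classes
are well defined; exactly duplicated columns are always equivalent.
Signatures are the cartesian product of the equivalence classes (capped,
with a warning, at 10,000). Perfect separation — common with strong
pooled effects — never aborts the search: separated fits fall back to
Jeffreys-prior (Firth) penalized likelihood, and both models of a
likelihood-ratio pair are refit penalized so the test statistic is
internally consistent.

`cv_rank_candidates()` scores each signature by stratified k-fold
repeated CV misclassification (default 5-fold × 10 repeats,
classification at probability 0.5 — Youden cutoffs are reserved for
validation) under three learners: logistic regression, random forest
(500 trees) and a linear-kernel SVM with default regularization; learner
hyperparameters are pinned for reproducibility since the source design
does not state them. Each probe inherits the minimum error over
signatures containing it and learners, and probes are ranked
lexicographically by (error ascending, |Δβ| descending, q ascending) —
the lexicographic reading of "maximal differences among minimal-error
models"; a joint weighting would need a weight the design never states.
The candidate set is the union of the top-15 ranked probes, up to three
additional probes with zero CV error on the NN-vs-AA sub-problem
(interpreted as zero misclassification in the same CV scheme), and the
probes whose external bisulfite-sequencing differences exceed 0.30 with
the array's direction; overlaps are deduplicated with a log message, so
26 is the default layout, not an invariant.

## Panels and validation

`build_design()` assembles samples × (markers, age, sex) with either raw
pyrosequencing percents or log10(x + 1) — the +1 offset is a package
choice so that a 0% measurement maps to 0; pyrosequencing zeros occur
and the design must remain finite. Features are standardized for the
penalized fits and the scaling stored.

`fit_penalized()` runs `glmnet` along its λ path with stratified folds
and picks λ at the minimum mean CV error. The CV loss is
**misclassification error** by default (deviance by argument). This is a
deliberate resolution of an ambiguity: "minimum mean cross-validation
error" most naturally denotes classification error, and under
misclassification loss `cv.glmnet`'s tie rule (largest λ attaining the
minimum) yields the sparsest model with minimal error, which is what
makes a two-marker panel recoverable from 26 candidates at n = 48 — a
property the test suite verifies on the generator. Under deviance loss
the λ-minimum systematically over-selects at this sample size.

`fit_panel_logistic()` is maximum-likelihood logistic regression with a
rank check (collinear panels are an error) and a Firth fallback on
separation (flagged, never silent). The Firth fit maximizes the
Jeffreys-penalized likelihood by Newton iteration with step halving to a
1e-8 step tolerance; it always exists and preserves score ordering.
`loocv_scores()` refits the panel for every held-out sample and pools the
out-of-fold probabilities into a single score vector; zero-variance
panel features are dropped once up front (log message) so the scoring
rule is identical across folds, and an all-constant panel scores every
sample at the training prevalence. The empirical ROC calls a sample
positive at score ≥ threshold over all observed thresholds; AUC is the
Mann–Whitney concordance with half ties (equal to the trapezoid area,
and property-tested against exhaustive pair counting at 1e-12); the 95%
AUC CI uses the DeLong variance; the Youden cutoff maximizes
sensitivity + specificity − 1 with a 1e-12 numeric tie tolerance and
ties broken toward higher specificity. Confusion metrics carry exact
Clopper–Pearson 95% CIs — the convention was chosen because it exactly
reproduces the printed intervals for 39/39 and 52/66 — and empty
denominators yield explicit `NA`, never NaN. Rank tests are exact for
small untied samples and tie-corrected normal approximations otherwise,
with zero differences dropped by the signed-rank convention; all-tied
input returns p = 1 with a warning.

One known behaviour deserves a note: pooled LOOCV scores of an
*uninformative* feature are anti-correlated with the held-out label
(leaving out a positive lowers the training prevalence and hence the
held-out prediction), so a null panel's LOOCV AUC sits at or below
chance rather than at 0.5. This is an inherent property of pooled LOOCV
scoring, visible in the SEPT9-like comparator of the pipeline report; it
is conservative in the direction that matters (a null marker never looks
informative).

## The synthetic generator: what it does and does not emulate

Individual betas are Beta(μ·φ, (1−μ)·φ) draws with per-probe baseline
means uniform on (0.05, 0.95) and precision φ = 60 (beta-value standard
deviation ≈ 0.06 at μ = 0.5, a realistic inter-individual spread for
serum cfDNA at modest coverage); planted probes shift the AN mean by a
signed Δβ (default |Δβ| = 0.20, 86.7% hypermethylated, matching the
direction split of the discovery analysis), with baselines drawn so both
group means stay inside (0, 1). Pool values are unweighted member means
("equal amounts of cfDNA"), perturbed on the logit scale
(σ = 0.10) — logit noise keeps pooled values in (0, 1) without
distorting small effects near the boundaries. Pyrosequencing is
100 × beta plus truncated Gaussian noise (σ = 5 percentage points); the
serum-vs-plasma offset is σ = 2 points. The array noise scale for pooled
cfDNA is not quantified in the source design; σ = 0.10 was chosen once
as the scale that keeps pool values essentially rank-identical to member
means (per-pool correlation > 0.95) while still reproducing the
pooled-vs-individual concordance bound (Pearson r ≥ 0.6) with a wide
margin — it is calibrated to that bound only, not to any deeper moment
of real array noise.

Default problem sizes are a package choice made for tractable runtimes:
10,000 probes and 100 planted DMPs for the full pipeline, 20,000 probes
with 200 planted effects and 14 + 14 pools for the FDR calibration
experiment (20 replicates), and 1,500 probes for the test-suite pipeline
runs. Probe count, effect size, noise scales and cohort composition are
all configuration knobs, not constants.

What the generator does **not** emulate: probe-level failure modes of
the array (cross-hybridization, SNP-under-probe artifacts), bisulfite
conversion chemistry, batch effects beyond the slide-randomization
design, cell-type composition shifts, correlated neighbouring CpGs, and
the long-tailed, bimodal baseline distribution of real methylomes
(baselines here are independent and uniform). Consequently, a passing
test suite demonstrates that the *statistical machinery* is correct and
calibrated under its stated model — FDR control with independent probes,
recovery of planted effects, concordance under the assumed noise — not
that the pipeline's operating characteristics transfer to real serum
cfDNA, where correlation structure and technical artifacts can inflate
error rates.

## Degenerate inputs and numerical conventions

* Beta values outside [0, 1], duplicated probe/sample ids, and unknown
  category levels are hard errors with the offending location named.
* Missing measurements are explicit `NA`s; downstream statistics drop
  them with a logged count, never encode them as out-of-range numbers.
* Beta-matrix TSV round trips are exact at the declared decimal
  precision (default 6 digits).
* Seeds are explicit everywhere; every generator and every CV routine
  derives an independent stream from its seed argument, and identical
  (configuration, seed) pairs reproduce byte-identical outputs.
* All empirical thresholds used by tests (Monte-Carlo tolerances, seed
  counts) were fixed from the generating model before being asserted.

## Known limitations

* SES enumerates equivalence classes from the final selected set only;
  it does not re-run the forward phase per signature, so extremely
  collinear designs may under-enumerate distinct minimal signatures.
* The moderated model assumes independent probes; the FDR calibration
  experiment inherits that assumption.
* Panel validation refits models on synthetic data; coefficient-level
  agreement with any externally reported decision rule is out of scope.
* The pipeline models the class design only (no covariate adjustment in
  discovery); hospital and age enter through the design checks, not the
  linear model.
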