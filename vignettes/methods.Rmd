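---
title: "Methods: matched-set protein marker discovery with protomark"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: matched-set protein marker discovery with protomark}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protomark)
```

## The problem

Large prospective cohorts bank blood samples years before any cancer
diagnosis. Nesting a matched case-control study inside such cohorts — each
future lung cancer case paired 1:1 with a control from the same cohort,
matched on age, sex, blood-draw date, and detailed smoking history — lets a
proteomics screen ask which circulating proteins already differ in the years
immediately preceding a clinical diagnosis. `protomark` implements the full
analysis chain for such a design: measurement-level preprocessing of
log2-scale relative abundance (NPX-like) values, per-protein matched
association models, a resampling-based discovery–replication selection
algorithm, stratified and lead-time trend analyses, incremental
discrimination over a baseline risk score, stability networks among the
markers, preclinical stage back-calculation, and post-diagnosis survival
models.

Because the cohort data such studies run on are access-restricted, the
package ships a first-class synthetic-study generator with planted,
recoverable effects. Every downstream stage is tested against it and against
small independent oracles (grid search, exhaustive enumeration, closed
forms).

## The matched association model

For a 1:1 matched set $s$ with case value $x_{s1}$ and control value
$x_{s2}$ of a standardized protein, the conditional likelihood contribution
is

$$
L_s(\beta) \;=\; \frac{e^{\beta^\top x_{s1}}}{e^{\beta^\top x_{s1}} +
e^{\beta^\top x_{s2}}}
\;=\; \operatorname{logit}^{-1}\!\bigl(\beta^\top d_s\bigr),
\qquad d_s = x_{s1} - x_{s2} .
$$

`fit_clogit()` maximizes $\prod_s L_s$ by Newton iterations on the within-set
differences $d_s$ with analytic gradient and Hessian (convergence when the
score's sup-norm falls below $10^{-8}$, at most 50 iterations, step-halving
on any likelihood decrease). Wald standard errors come from the observed
information; confidence intervals are $e^{\beta \pm 1.96\,\mathrm{se}}$ and
p-values are two-sided normal, so the interval and the test agree by
construction. $e^\beta$ is the odds ratio per standard deviation of the
(log2, cohort-standardized) protein, the effect scale used throughout.

Only 1:1 sets are supported: the design is 1:1 throughout, and the
difference parameterization makes the likelihood exact without general m:n
machinery. Monotone likelihoods (every non-zero within-set difference of one
sign) have no finite maximizer and raise an error naming the covariate, and
sets missing the protein in either member are dropped per protein, with the
usable set count reported. Covariates that are constant within every set
difference out of the likelihood and are removed before fitting, so a
"smoking-adjusted" model with perfectly matched smoking covariates equals
the crude one exactly.

The smoking-adjusted variant enters cigarettes/day, years smoked, and years
since cessation as continuous covariates; the continuous (untransformed)
coding was chosen because categorized versions discard within-category
contrasts that matched sets are specifically able to exploit.

## Preprocessing rules

Three measurement-level rules are applied, in this order:

1. **LOD substitution.** Values censored below an assay's limit of detection
   are replaced by $\mathrm{LOD}/\sqrt{2}$, the standard substitution for
   left-censored relative-abundance data. The below-LOD mask is retained,
   and assays with $\ge$ 20% of values below LOD are flagged as failing QC.
2. **Duplicate resolution.** Proteins assayed on two panels keep the assay
   with the *lowest missingness*, breaking ties by *highest variance*
   (computed where all duplicates were measured). Missingness dominates
   because a sparser assay costs matched sets outright, while variance only
   orders assays of equal usability.
3. **Within-cohort standardization.** Each protein is centered and scaled to
   unit SD within each cohort over non-missing values, after the two rules
   above. All samples (cases and controls) enter the standardization; the
   alternative (controls only) changes estimates negligibly in a 1:1 design
   and would make the case scale depend on the control sampling.

## Multiplicity: the effective number of tests

Protein panels are highly correlated, so a Bonferroni correction at the raw
protein count is too strict. The effective number of tests (ENT) is the
number of principal components of the protein correlation matrix needed to
explain 95% of the variance; the discovery threshold is $0.05/\mathrm{ENT}$.
Missing entries are mean-imputed (zero after standardization) solely for the
eigendecomposition — this shrinks sample correlations slightly toward zero
and is therefore conservative for the ENT (more components, stricter
threshold). The ENT is computed once per selection run on the full
standardized matrix of the protein set in play, not once per resampling
iteration: the per-iteration value differs negligibly (the discovery set is
a 70%+ subsample of the same samples) and a fixed threshold makes pass
frequencies comparable across iterations.

## The resampling discovery–replication algorithm

A single random split into discovery and replication halves is noisy: which
borderline markers "replicate" depends heavily on the split. Instead, in
each of `n_iter` iterations (500 by design; scaled-down runs are used in
tests) the matched *sets* — never individual members — are split 70/30
within each cohort, with designated cohorts forced wholly into discovery
(in the emulated design, the two cohorts whose data chose the assay panels
for the rest). A protein passes an iteration if its discovery p-value is
below $0.05/\mathrm{ENT}$ and its replication p-value below 0.05; proteins
passing at least 50% of iterations are selected.

Two deliberate choices:

- **Sign concordance** between the discovery and replication estimates is
  required by default (toggleable). Replication of an *association* without
  direction would count a risk marker replicated by a protective signal.
- **Missing-data rule:** a protein enters an iteration only when at least
  `min_sets_per_side` (default 25) complete sets exist on each side;
  borderline sample sizes otherwise produce unstable separations in small
  replication halves.

Per-cohort discovery counts use R's `round()` (round-half-to-even), with the
remainder to replication. The whole run is a pure function of the seed, and
the iteration log records the cohort composition of every split so the
forced-cohort and set-integrity invariants can be asserted after the fact.

The single split-sample variant (`single_split_select()`) fixes the split at
cohort boundaries and uses BH-FDR < 0.05 in discovery (the smaller fixed
discovery set has less power, so ENT-Bonferroni would be too strict) with
p < 0.05 in replication; `compare_selections()` summarizes the overlap
between the two approaches.

## Stratified estimates, heterogeneity, and trend

Stratum-specific odds ratios use the case's attribute (histology, stage,
lead-time category `<1`, `1–2`, `2–3` years) or the set's shared attribute
(cohort, smoking status). Heterogeneity is tested by Cochran's Q on the
stratum log ORs with inverse-variance weights against $\chi^2_{k-1}$, and
ordinal strata additionally get an inverse-variance-weighted linear
regression of log OR on the category score with a normal test on the slope.
The paper-style contrast of interest — markers of imminent disease grow
stronger closer to diagnosis — appears in the generator as a negative
`beta_lead` and is recovered as a larger OR in the `<1y` stratum with
`p_trend < 0.05`.

## Incremental discrimination

`delta_auc()` reports the rank-concordance (Mann–Whitney, ties = ½) AUC of a
baseline questionnaire-style risk score and of the linear predictor from an
unconditional logistic model of case status on baseline score plus protein.
The two-variable combiner is the minimal construction that answers "does the
protein add discrimination?"; no cross-validation is applied, since with two
degrees of freedom the optimism is negligible relative to the differences of
interest. The AUC is computed on the matched sample as-is and is therefore
*conditional on the matched design* — matching on smoking makes controls
more case-like than population controls, so absolute AUCs here are not
population discrimination estimates; only differences are interpretable.

## Stability networks

Relationships among markers are modeled on proteins residualized (OLS) for
age, sex, cohort, and smoking status. The published analysis names its
residualization covariates inconsistently across methods text and figure
caption; the set used here is the union of the demographic covariates, with
the "all other proteins" conditioning realized by the precision matrix
itself, which is what a partial-correlation network means. Separately among
cases and controls, a graphical lasso (block coordinate descent, implemented
in C++) estimates a sparse inverse covariance on random 50% subsamples; an
edge's stability is the fraction of subsamples where its precision entry is
non-zero. The penalty is chosen by a StARS-style instability criterion
(monotonized edge-selection instability $\le$ 0.05 over a log-spaced grid
from the largest absolute off-diagonal correlation down to a tenth of it),
and edges with stability $\ge$ 0.9 are called stable. Subsample fraction
(50%), resample count (100), threshold (0.9) and instability target (0.05)
are the standard stability-selection defaults and all configurable.

## Clinical course

**Stage at blood draw.** Given mean preclinical sojourn times indexed by
stage, sex, and histology, the estimated stage at draw follows a
deterministic backward walk: subtract the diagnosed stage's mean sojourn
time from the lead time and step down a stage while the remainder is
positive; the lead time exceeding the whole preclinical window returns the
lowest modelled stage. A deterministic expected-path rule was chosen over a
stochastic dwell-time model because only mean sojourn times are available as
inputs; with full dwell distributions a probabilistic back-calculation would
be the natural extension. The packaged sojourn table
(`synthetic_sojourn_table()`, also shipped as
`inst/extdata/sojourn_synthetic.tsv`) is a clearly-labelled synthetic
stand-in with the qualitative structure of published natural-history
estimates; real estimates are supplied by the user as a delimited table.

**Survival.** Post-diagnosis mortality is modeled by Cox regression among
cases with the baseline hazard stratified by cohort × sex, adjustment for
age, Efron tie handling, and a protein × lead-time interaction so the
protein's main effect is its log hazard ratio at the moment of diagnosis.
This is a standard fit and is delegated to `survival::coxph()`.

## The synthetic-study generator

`generate_study()` emulates the design quantities of a six-cohort nested
case-control study: the default configuration has the published cohort set
counts (731 sets in total), 1162 proteins on 14 panels with 484 proteins
(6 panels) measured in every cohort and the remainder only in the two
full-library cohorts, 112 proteins duplicated on a second panel, lead times
uniform on [0, 3] years, and below-LOD censoring at a pooled 5% quantile.
Histology, stage, sex, age and smoking marginals approximate the published
cohort description (e.g. 33% female, 54%/46% current/former smokers); only
marginal realism is attempted.

Protein values for the two members of a pair are drawn from a bivariate
normal with within-pair correlation 0.2 (a stand-in for the residual
similarity induced by matching on smoking; configurable) and unit marginal
SD around protein-specific baselines. The case label within a pair is then
assigned *retrospectively* with probability
$e^{\eta_1}/(e^{\eta_1}+e^{\eta_2})$, where
$\eta_i=\sum_j \beta_j(L)\,x_{ij}$ and
$\beta_j(L)=\beta_{0j}+\beta_{\mathrm{lead},j}L$. Under this mechanism the
1:1 conditional-logistic model holds *exactly* with the planted
coefficients — the estimand equals the planted effect by construction, which
is what makes unbiasedness and coverage checks meaningful. A prospective
incidence-density simulation of the full cohorts would be more realistic but
would make the planted marginal log OR only approximately equal to the
fitted estimand.

What the generator does **not** emulate: assay plate effects and bridging
normalization, correlated protein blocks (proteins are independent unless a
precision structure is planted), non-uniform lead-time distributions, and
informative missingness beyond panel availability and LOD censoring.
Passing tests therefore demonstrate correctness of the estimators and
algorithms under the stated model, not robustness to those real-data
features.

## Numerical choices and degenerate inputs

- Newton tolerance $10^{-8}$ on the score sup-norm; vectorized univariate
  fits used inside the resampling algorithm cap steps at ±2 and declare
  estimates with $|\hat\beta| > 12$ non-converged (excluded from that
  iteration) rather than erroring mid-run.
- An assay with LOD = 0 and censored values substitutes 0 with a warning;
  zero within-cohort variance excludes a protein from that cohort with a
  flag; all-constant proteins are excluded from the ENT eigendecomposition
  with a warning.
- The graphical lasso declares failure on non-positive-definite precision
  estimates rather than silently regularizing further.
- Ties in the duplicate-resolution variance criterion resolve to the first
  assay in column order (deterministic).
- One global pipeline seed derives per-stage seeds by a stable hash of the
  stage name, so disabling one stage never shifts another stage's draws.

## Problem sizes used in the automated checks

The test-suite and the acceptance script use scaled-down study conditions
chosen to give the property checks high power: 500 simulated studies of 700
sets for bias/coverage of planted ORs 0.74/1.31/2.43; selection runs with
300 proteins, 400 sets over four cohorts (one forced), and 100 iterations
across 10 planted and 10–20 null seeds; networks of 8 proteins at n = 300
with 50 subsamples; Cox recovery of (0.3, −0.1) at 2000 cases over 10
seeds; and a 1000-case stage-shift oracle comparison. These sizes are the
package's standing choices for its own verification and are stated here so
the reported rates can be reproduced exactly.

## Known limitations

- Only 1:1 matched sets; no Firth or exact conditional inference for
  separated small strata.
- The ENT's mean-imputation bias is conservative but unquantified for very
  missing panels.
- Absolute discrimination metrics are design-conditional (see above).
- The stage back-calculation is deterministic in mean sojourn times and
  ignores dwell-time dispersion.
- Stage-adjusted survival models are intentionally out of scope; the Cox
  model does not account for stage at diagnosis.
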