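# protomark

Protein marker discovery in 1:1 matched case-control studies nested within
prospective cohorts.

Cohort biobanks make it possible to ask which circulating proteins already
differ in blood drawn up to a few years *before* a clinical cancer
diagnosis. The studies that answer this question share a characteristic
design — each future case matched 1:1 to a control from the same cohort on
age, sex, blood-draw date, and detailed smoking history, with proteins
measured on multi-panel affinity assays (log2-scale NPX-like units) whose
panel coverage differs by cohort. `protomark` implements the analysis chain
for that design end to end, for epidemiologists and biostatisticians running
or re-analyzing such screens:

- **Preprocessing** — below-LOD substitution by LOD/√2, duplicate-assay
  resolution (lowest missingness, then highest variance), within-cohort
  standardization, and a below-LOD QC report (< 20% rule).
- **Matched association models** — conditional logistic regression fit by
  Newton iterations on within-set contrasts. For a set *s* with
  case/control difference *d_s*, the likelihood is
  ∏_s logit⁻¹(βᵀd_s); the package reports the odds ratio per SD,
  e^(β±1.96·se) confidence intervals, and Wald p-values, plus
  smoking-adjusted variants and cross-sectional protein-on-smoking linear
  models.
- **Multiplicity** — the effective number of tests (ENT: principal
  components explaining 95% of protein variance) as a Bonferroni
  denominator, and BH-FDR.
- **Selection** — a resampling discovery–replication algorithm: repeated
  cohort-balanced 70/30 splits of matched sets (designated cohorts forced
  into discovery), a protein selected when discovery p < 0.05/ENT and
  replication p < 0.05 in ≥ 50% of iterations; plus a single split-sample
  sensitivity variant and overlap comparison.
- **Characterization** — stratified ORs with Cochran's Q heterogeneity and
  lead-time trend tests; incremental AUC over a baseline risk score;
  graphical-lasso stability networks of residualized proteins in cases and
  controls (StARS-style penalty selection, C++ core).
- **Clinical course** — deterministic sojourn-time back-calculation of
  stage at blood draw, and Cox survival models stratified by cohort × sex
  with a protein × lead-time interaction.
- **Synthetic studies** — a generator of multi-cohort matched studies with
  planted, exactly recoverable effects, so the whole pipeline is testable
  without access-restricted cohort data.

## Worked example

The packaged demo configuration simulates a three-cohort study (250 matched
sets, 40 proteins, 6 duplicated assays, LOD censoring) with two planted
markers — `P0001` at OR 2.4 per SD and `P0002` at OR 0.74 per SD — and runs
every stage:

```r
library(protomark)
out <- tempfile()
man <- run_pipeline(system.file("extdata", "demo_config.yaml",
                                package = "protomark"), out)

sel <- read.delim(file.path(out, "selection.tsv"))
head(sel[order(-sel$joint_pass_freq), ], 3)
#>   protein discovery_pass_freq replication_pass_freq joint_pass_freq selected
#> 1   P0001                   1                  0.74            0.74     TRUE
#> 2   P0002                   1                  0.34            0.34    FALSE
#> 3   P0003                   0                  0.02            0.00    FALSE

assoc <- read.delim(file.path(out, "associations.tsv"))
head(assoc[order(assoc$p), c("protein", "or_sd", "ci_low", "ci_high", "p")], 2)
#>   protein     or_sd   ci_low   ci_high            p
#> 1   P0001 1.9632657 1.547475 2.4907751 2.760841e-08
#> 2   P0002 0.5936617 0.474780 0.7423106 4.791553e-06
```

Reading the output: the strong planted marker passes the ENT-corrected
discovery threshold in 100% and the replication threshold in 74% of the 50
resampling iterations, so it clears the ≥ 50% joint rule and is selected.
The weaker inverse marker replicates in only 34% of iterations — real
association (OR 0.59, p ≈ 5 × 10⁻⁶ in the full sample) but, at this sample
size, not reproducible enough for the algorithm's standard, which is exactly
the conservatism the resampling design is meant to provide. The run manifest
reports the ENT (37 here) and the estimated fraction of cases still at stage
≤ 2 at blood draw (0.68 with the packaged synthetic sojourn table); the
other stage tables (`stratified.tsv`, `discrimination.tsv`,
`network_edges.tsv`, `survival.tsv`) hold the per-protein stratified ORs
with heterogeneity/trend p-values, ΔAUC over the baseline risk score,
stability-network edges, and post-diagnosis hazard ratios.

All stage functions are also usable directly, e.g.:

```r
st <- generate_study(sim_config(seed = 1))   # full-scale synthetic study
pp <- preprocess_study(st)
fit_clogit(pp$matrix[, "P0001"], st$subjects, protein = "P0001")
```

## Vignette

`vignettes/methods.Rmd` documents the statistical model, every tunable
parameter with its default and rationale, what the synthetic generator does
and does not emulate, numerical edge-case handling, and known limitations.
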