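---
title: "The total genotype score model of endurance trainability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The total genotype score model of endurance trainability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tgscore)
```

## The scientific problem

Individuals differ widely in how much their cardiorespiratory fitness
improves under an identical endurance programme. `tgscore` implements a
candidate-panel analysis of that heterogeneity: given a biallelic SNP panel
genotyped on a small training cohort and Cooper 12-minute-run distances
measured before and after training, it asks whether the number of
"favorable" alleles a participant carries explains their percentage
improvement.

The analysis proceeds in fixed stages, each exposed as a pipe-friendly
function and orchestrated by `run_discovery()`:

1. **Panel QC.** Replicate probe readings are normalised to the forward
   strand (`normalize_orientation()`); calls whose replicates disagree are
   blanked and participants with excessive missingness are dropped
   (`filter_inconsistent()`); SNPs without allelic variation in the cohort
   are removed (`remove_monomorphic()`).
2. **Response phenotype.** Each training-arm participant's percentage
   improvement is `100 * (d8 - d0) / d0` from individual distances;
   participants strictly above the arm's mean percentage improvement are
   *responders* (`dichotomize_responders()`). Group summaries average
   individual percentages — the mean of individual percent changes, which
   differs from the percent change of group means whenever baselines vary.
3. **Screen.** Pearson's chi-square (no continuity correction) on the
   2 x 2 responder-by-allele table of every polymorphic SNP
   (`chi_square_screen()`), banded at p <= 0.05 (primary) and
   0.05 < p <= 0.075 (secondary).
4. **Confirmation.** One-way ANOVA of percentage improvement across
   genotype groups for banded SNPs, gated by Levene's test
   (`anova_confirm()`).
5. **Population check.** Cohort genotype counts of confirmed SNPs are
   compared with Hardy-Weinberg expectations at published population
   allele frequencies by Fisher's exact test; deviating SNPs are excluded
   (`flag_population_outliers()`).
6. **Scoring and regression.** Each retained SNP contributes 0/1/2 copies
   of its favorable allele (`score_genotype()`); totals per participant
   (`sum_scores()`) are regressed on percentage improvement
   (`score_regression()`), reporting slope, r, R², and the two-sided
   slope p-value.

## Model and assumptions

The scoring model is deliberately the simplest additive one: an unweighted
allele count over retained SNPs. It assumes (i) biallelic SNPs with
independent marginal effects (no linkage disequilibrium or epistasis is
modelled), (ii) equal effect per favorable allele across SNPs, and
(iii) a linear relation between the count and the percentage response. The
regression p-value assumes Gaussian residuals.

Hardy-Weinberg expectations use genotype proportions p², 2pq, q² from the
reference-allele proportion; the Fisher comparison rounds expected counts
to integers (the exact test is defined on integer tables — the smallest
perturbation of the stated comparison) and falls back from the 2 x 3
genotype table to the 2 x 2 allele table whenever a genotype class has a
rounded expectation of zero, which is common at cohort sizes in the tens.
The two-sided exact p sums the probabilities of all tables with the fixed
margins not exceeding the observed table's probability.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `screen_alpha` | 0.05 | primary screen band (p <= alpha) |
| `secondary_max` | 0.075 | upper edge of the near-significance band carried to confirmation |
| `confirm_alpha` | 0.05 | ANOVA confirmation and Levene gate level |
| `fisher_alpha` | 0.05 | population-frequency exclusion level |
| `model` | `"allele"` | contingency construction; `"genotype"` available |
| `correction` | `"none"` | optional Bonferroni/BH on the screen for sensitivity analysis |
| `max_missing` | 0.2 | participant missingness ceiling in QC |
| `missing_policy` | `"zero"` | missing genotype at a retained SNP scores 0, reported in `n_missing` |

No multiple-testing correction is applied by default: the design treats the
ANOVA confirmation, the population-frequency exclusion and the additive
structure of the final score as the guards against false positives, and
exposes `correction = "bonferroni"`/`"bh"` to quantify how conclusions
depend on that choice. On a null panel the primary band captures about
`screen_alpha` of SNPs, growing linearly with panel size — intended,
documented behaviour.

Training load helpers follow the session-RPE convention: session load =
duration (min) x intensity (%VO2max), with intensity mapped linearly from
the Borg CR-10 sRPE (x10, so sRPE 6–7 is 60–70%); weekly load = mean
session load x sessions; total load sums weekly loads (accommodating taper
and test weeks). The sRPE-to-intensity mapping is pluggable.

Cohen's d for within-group change is standardised by the group's baseline
SD. This choice reproduces the conventional effect-size readings of
training studies at 2-decimal reporting precision; change-score or pooled
standardisation can be substituted by passing a different `sd`.

## The synthetic cohort generator

Because candidate-panel cohorts of this design are rarely deposited, every
stage is validated by parameter recovery on synthetic cohorts
(`simulate_cohort()`). The generator's defaults encode the study
conditions the pipeline targets:

* arms of 21 training / 24 control participants, baselines ~N(2.22, 0.48²)
  km and ~N(2.06, 0.37²) km;
* a 1,000-SNP panel with 28.5% monomorphic SNPs (fixed for one allele,
  emulating low-frequency alleles unrepresented in a small cohort) and
  Hardy-Weinberg genotypes at alternate-allele frequencies uniform on
  \[0.1, 0.9\];
* 18 causal SNPs with equal additive per-allele effects at favorable-allele
  frequency 0.5; the effect, residual SD and intercept are derived so the
  training-arm percentage improvement has mean 11.51, SD 9.09 and planted
  score-response R² 0.85;
* control-arm changes ~N(1.55, 6.98²)%;
* week-4 distances interpolated at 0.6 of the week-8 change (partial
  adaptation mid-programme);
* optional artifacts: replicate-probe disagreements at a configured rate,
  outright missingness, and wholesale corruption of named participants so
  that QC demonstrably removes them.

All randomness flows from one seed; identical config and seed reproduce the
cohort byte-for-byte through `write_cohort()`/`read_cohort()`. Measured
quantities are rounded at generation to physically sensible precision
(0.1 m for distances, 0.01 min for durations), which also makes the
plain-text round trip exact.

What the generator does **not** emulate: linkage disequilibrium between
SNPs, genotyping-intensity artefacts (only their downstream symptom,
replicate disagreement), non-Gaussian response noise, dropout over the
programme, and seasonal/behavioural confounds. Passing recovery tests
therefore show the pipeline's statistics are correct under its own model,
not that the model captures every property of field data.

## Numerical and design choices

* Allele strings are uppercase A/C/G/T with explicit `NA` for missing;
  genotypes are unordered pairs stored alphabetically. Missing calls are
  never imputed.
* Palindromic (A/T, C/G) SNPs cannot be strand-resolved from sequence
  alone; reverse-orientation readings at such SNPs are trusted as supplied
  and flagged with a warning. The simulator draws only non-palindromic
  allele pairs, as genotyping panels do by design.
* The participant-drop missingness ceiling defaults to 20% of panel SNPs
  and is configurable; the QC audit lists every blanked call and dropped
  participant with its reason.
* Degenerate contingency tables (a zero margin) score chi-square 0, p 1,
  band `none`. Genotype groups below 2 members are dropped from the ANOVA
  by default (`small_groups = "merge"` merges them into the heterozygote
  group); fewer than two groups afterwards yields p 1, not confirmed.
* Favorable-allele ties (identical frequencies in both responder classes)
  leave the SNP unresolved and unscored, with a warning.
* The retention rule is: screen band primary *or* secondary, AND ANOVA
  p <= 0.05 with Levene p > 0.05, AND not population-excluded, AND a
  resolved favorable allele. Secondary-band SNPs can therefore be retained
  on ANOVA evidence, mirroring candidate tables where a
  chi-square p slightly above 0.05 coexists with a confirming ANOVA.
* Screen output ordering is deterministic: chi-square p ascending,
  lexicographic rsid tie-break.
* Scoring restricts to classified (training-arm) participants; the
  regression inner-joins scores and responses so only complete pairs enter.

Problem sizes used by the validation suite are chosen for stable Monte
Carlo behaviour at interactive runtimes: 1,000-replicate R² recovery at
the 17-participant study scale, 300-replicate slope/allele recovery at
100 per arm, and three full-panel null cohorts for screen calibration.

## Known limitations

The headline regression is fitted to the same cohort in which the SNPs
were selected for association with above-average response. On null panels
(no planted effects) the screen-plus-confirmation stages still retain a
small set of false positives, and the in-sample regression of their summed
score on the response is reliably "significant" — a direct illustration of
selection circularity (winner's curse). The pipeline reports this
behaviour honestly rather than correcting it, because reproducing the
published procedure is the package's purpose; any confirmatory use of the
score requires an independent validation cohort or pre-registered SNP set.
Relatedly, with many equal-effect causal SNPs the responder-table
favorable-allele assignment has an accuracy ceiling set by the per-SNP
correlation bound 1/sqrt(m) — at 18 causal SNPs and 100 training
participants about 97% of causal SNPs get the correct favorable allele,
and misassigned SNPs attenuate the recovered slope slightly when scored
with assigned (rather than true) alleles.

The ANOVA confirmation treats genotype as categorical and is gated on
homogeneity of variance only; normality within genotype groups is not
tested at typical group sizes (2–10), where such tests are uninformative.

## A worked example

```{r, eval = FALSE}
library(tgscore)

cohort <- simulate_cohort(sim_config(seed = 42))
run <- run_discovery(cohort)
print(run)
render_table1(run)
autoplot(run$regression)
```
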