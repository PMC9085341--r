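---
title: "Methods: DRG cost grouping for discharge abstracts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: DRG cost grouping for discharge abstracts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drgcost)
```

## The analysis in one paragraph

Hospitalisation costs inside one adjacent DRG (here: cerebral ischemic
disease) are right-skewed and heterogeneous. The workflow asks, in order:
is the group heterogeneous enough to subdivide (cost CV > 1)? which patient
factors drive cost (rank tests, then an adjusted gamma regression)? how
should patients be partitioned into cost groups (an exhaustive-CHAID
regression tree over the significant factors, with CART as a baseline)? are
the groups homogeneous and separated (per-group CV ≤ 1; Kruskal-Wallis)?
and what should each group's payment standard be (median as standard cost,
`P75 + 1.5·IQR` as upper limit, cases above it as excess)?

## Record cleaning

`apply_exclusions()` applies four criteria in a fixed order — missing or
invalid required fields; primary diagnosis or procedure codes outside the
grouping scheme; length of stay above 60 days; total cost strictly below
the 1st or strictly above the 99th percentile — counting each record only
under the first criterion it violates, so the exclusion log is additive and
reproducible. The percentile bounds are computed on the cohort surviving
the first three criteria, with linear-interpolation quantiles (type 7;
configurable, since the convention is software-dependent and unstated in
most reports). Severity assignment follows the MCC&CC rule: a record has
MCC (or CC) if any secondary diagnosis is on the MCC (CC) inclusion table
and the primary diagnosis is not on that code's exclusion list, with MCC
taking precedence.

Age bands are 0–17, 18–65 and >65 with inclusive upper bounds. The youngest
band admits age 0: published tables sometimes label it "1–17", but the
cohort's reported age range starts at 0, so 0 belongs to the child band.
Blank secondary-diagnosis lists are legitimate (no comorbidity), not
missing data.

## The synthetic cohort generator

No public discharge data exist for this population, so `generate_cohort()`
draws admissions whose distribution matches the published cohort structure:

* **Covariates** are drawn independently from the published prevalences
  (male 61.78%; age bands 1.31/43.64/55.05%; MCC/CC/Non-CC
  22.43/57.69/19.89%; emergency admission 54.82%; long stay 4.09%;
  discharge home/transfer/death/other 96.66/1.21/1.75/0.38%; insured
  11.63%; allergic 48.65%). Only marginals are published; independence is
  the simplest structure matching all of them. This is also the generator's
  main idealisation — see *Limitations*.
* **Costs** follow a multiplicative model: each record's expected cost is a
  baseline times the product of its levels' multipliers, which are the
  published adjusted cost ratios (e.g. long stay 4.23, age >65 2.63, MCC
  2.25, emergency 1.20); insurance and allergy carry multiplier 1, matching
  the adjusted analysis in which they showed no effect. Realised costs are
  gamma draws with constant shape, the same family the regression fits.
* **Calibration is analytic, not tuned.** With independent covariates,
  `E[cost] = b·∏ᶠ E[mᶠ]` and `1 + CV² = (1 + 1/k)·∏ᶠ E[mᶠ²]/E[mᶠ]²`, where
  `mᶠ` is factor f's multiplier under its category probabilities, `b` the
  baseline and `k` the gamma shape. `calibrate_generator()` solves these two
  moment identities for `b` and `k` so the cohort hits mean 17,206.09 RMB
  and CV 1.18 in expectation (giving b ≈ 3,442 RMB, k ≈ 1.563). Nothing was
  adjusted after looking at test results.
* **Length of stay** is a log-normal matched by moments to 10.70 ± 8.61
  days, drawn truncated to [1, 30] or [31, 60] according to the drawn
  long-stay flag so derived features reproduce the drawn categories
  exactly; only mean and SD are published, and a truncated log-normal is
  the standard right-skewed choice. Truncation shifts the realised moments
  a few percent above the nominal targets.
* **Cost components** follow the published per-year composition shares with
  Dirichlet jitter (concentration 60 — shares wobble a few points per
  record), rounded to the cent with the residual folded into the largest
  component so components sum exactly to the total.
* **Code tables** are synthetic: secondary-diagnosis codes partitioned into
  MCC/CC/neutral thirds with a sparse exclusion map (about 10% of inclusion
  codes exclude one or two primary codes). They exercise the assignment
  logic; they are not the licensed national lists.

### What the generator emulates — and what it does not

The published mean, CV and LOS moments all describe the *cleaned* study
cohort (N = 5204), so the generator emulates the cleaned cohort, and the
synthetic pipeline default does not re-trim it (`pipeline_config()` uses
`trim = c(0, 100)` for the synthetic source; the 1/99 rule remains the
default of `apply_exclusions()` for raw file data). This matters more than
it may seem: percentile trimming removes exactly the costly tail that
pushes the CV above 1, and re-trimming an already-clean cohort drops its CV
from ≈ 1.18 to ≈ 0.89, below the subdivision threshold. Conversely, a
cleaned cohort with CV 1.18 implies an even heavier untrimmed tail.

Because covariates are independent, real correlations are absent: in the
study cohort nearly all children were Non-CC outpatient admissions (one
published group is "Non-CC, outpatient, <18 years" with n = 56), whereas
the generator spreads its ~68 children across severity levels, leaving
about 13 per severity stratum — too few to split off under the minimum
child size. Passing tests therefore demonstrate that the machinery recovers
planted structure, not that it reproduces the published tree leaf-for-leaf
(which no synthetic cohort built from marginals could).

## Univariate screening

`mann_whitney()` uses midranks, the normal approximation with tie-corrected
variance, and two-sided p-values; the continuity correction is off by
default (conventional asymptotic output at these sample sizes) and
configurable. `kruskal_wallis()` reports the tie-corrected H with a
chi-square reference. Both report per-level rank means, whose size-weighted
average is always (N+1)/2 — a useful internal check. The published
univariate table also prints a mean ± SD row for raw length of stay with an
unlabelled test statistic; only the dichotomised long-stay (>30 days)
comparison is reproduced, since the raw-LOS test cannot be identified from
the report.

## Gamma regression and marginal means

`fit_gamma()` fits `cost ~ sex + age_band + social_insurance +
admission_route + cc_level + long_stay + discharge_mode` with a log link by
IRLS (relative deviance change < 1e-8, at most 100 iterations), Pearson
chi-square dispersion, and Wald intervals on the log scale exponentiated to
cost ratios — matching conventional commercial-package output. Marginal
means average *response-scale* predictions over a balanced equal-weight
grid of the other factors: balanced (not observed-margin) averaging is
indicated because the published marginal means (≈ 27k–42k RMB) far exceed
raw group means, which only happens when rare expensive levels (MCC, long
stay, death) get equal weight. With a log link and main effects only, the
ratio of a level's marginal mean to its reference's equals its cost ratio
exactly — an identity the tests verify, and the reason reported differences
are computed from unrounded means.

## The exhaustive-CHAID tree

For each candidate predictor at a node, `merge_categories()` seeks the
partition of its observed categories whose one-way ANOVA against cost is
most significant. Every predictor in this domain has at most four
categories, so the search scores *all* admissible partitions exactly — all
set partitions for nominal predictors, all contiguous-interval partitions
for ordinal ones (age bands are ordinal; severity is nominal by default
with an ordinal toggle). Beyond six categories the implementation falls
back to the classical sequential scheme (repeatedly fuse the least
significantly different admissible pair, remembering the best partition
seen); the exact search was chosen because the sequential heuristic misses
the optimum on roughly a fifth of small noisy inputs, which would make the
tree depend on merge order rather than on the data.

`select_split()` Bonferroni-adjusts each predictor's best p-value by the
number of ways its c observed categories can form the k merged groups
(Stirling number S(c,k) for nominal, C(c−1, k−1) for ordinal), rejects
candidates whose children would fall below the minimum child size, and
keeps the most significant predictor if its adjusted p ≤ α. Note one
consequence of this contract: if a predictor's *optimal* partition isolates
a stratum smaller than the minimum child size, that predictor is dropped at
that node even if a coarser admissible partition would have been
significant.

Numerical choices: split p-values are computed and compared on the log
scale (`pf(..., log.p = TRUE)`) because strong effects underflow double
precision and partitions must still be ranked; genuine ties prefer the
coarser partition, then the declared predictor order — both for
determinism. Degenerate ANOVA cases are defined explicitly (no between
variance → p = 1; zero within variance with distinct means → p = 0).
Defaults — α = 0.05, Bonferroni on, minimum parent 100, minimum child 50,
depth 5 — are configurable and sized to make 5–12 leaves plausible at
n ≈ 5,000. The long-stay indicator is excluded from the default predictors:
length of stay varies too much across hospitals to define payment groups.

`grow_cart()` is the baseline: binary splits over all binary category
partitions minimising within-node SSE, same size limits, with a
minimum-improvement threshold (`cp`, default 0.01 of the root SSE) as
pre-pruning. Model comparison reports the Pearson correlation between leaf
means and observed costs, the mean absolute error, the SD of errors
(interpreting the published "standard deviation" column as the SD of
prediction errors), and the leaf count.

## Validation and payment standards

`premise_check()` and `validate_grouping()` use the strict CV rule
(subdivide iff CV > 1; a group is homogeneous iff CV ≤ 1) with the sample
(n−1) standard deviation — the divisor is unstated in most reports and
configurable conventions would change CVs by under 1% at these sizes.
Between-group separation uses the Kruskal-Wallis test from the screening
module. `payment_standard()` computes quantiles by linear interpolation
(configurable to the inclusive convention of common commercial packages),
the fence `P75 + 1.5·IQR`, and counts excess cases with strict inequality
(cost > upper limit); currency is rounded to the cent, half-to-even.
Excess counting operates on the analysis cohort (post-cleaning), the same
data every other stage sees.

On synthetic cohorts the per-group CVs land near 1, with several slightly
above — unlike the published 9-of-10-below-1 — because the generator's
within-cell dispersion is a constant gamma shape calibrated to the overall
CV, and the long-stay factor (cost ratio 4.23) is deliberately not a
grouping variable, leaving its full spread inside every group. This is an
honest property of the independence-based generator, not of the method.

## Problem sizes and determinism

The test suite and the analysis scripts work at the study scale (cohorts of
5,204; 50,000 for convergence checks of prevalences), with 40 seeded
replicates for the parameter-recovery suite and 2,000 replicates for the
rank-test type-I-error calibrations; brute-force oracles (all set
partitions, exhaustive SSE search, exact permutation enumeration) run on
inputs of at most ~20 records where enumeration is exact. The pipeline is a
pure function of (input, configuration, seed): no timestamps or environment
state reach any report, so identically seeded runs are byte-identical.

## Known limitations

* Independent covariates: no age-severity or severity-discharge
  correlation, so published leaf compositions cannot be reproduced exactly.
* Synthetic code tables exercise the MCC/CC logic but are not the licensed
  national inclusion/exclusion lists, and code syntax is not validated.
* One published upper limit (group 1) differs by one cent from the fence
  recomputed from its published P75/IQR — the source evidently used
  unrounded quantiles; this package computes fences from unrounded
  quantiles and rounds last.
* The gamma model is a single main-effects specification; interactions,
  model selection and alternative families (log-normal, Tweedie) are out of
  scope.
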