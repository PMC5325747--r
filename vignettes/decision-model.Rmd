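---
title: "A decision-analytic QALY model of MVD versus SRS for trigeminal neuralgia"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A decision-analytic QALY model of MVD versus SRS for trigeminal neuralgia}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tndecide)
```

## The question and the model

Medically refractory trigeminal neuralgia can be treated by microvascular
decompression (MVD, an open posterior-fossa operation) or stereotactic
radiosurgery (SRS, focused radiation lesioning of the nerve). Both relieve
pain; they differ in initial cure rate, complication profile, and durability.
Because no adequately powered randomized comparison exists, the comparison
here is decision-analytic: each strategy is a chance tree over the outcomes a
patient can experience, each terminal outcome is valued in quality-adjusted
life years (QALYs), and the strategies are compared on expected QALYs over a
follow-up horizon.

Pain outcomes are graded on the Barrow Neurological Institute (BNI) pain
scale, collapsed to four states: BNI I (pain-free off medication), BNI II
(occasional pain, no medication), BNI III (pain controlled with medication)
and BNI IV-V (inadequately controlled or unrelieved pain, merged because the
pooled literature rarely separates them). States III and IV-V imply
maintenance medication. Utilities anchor BNI I at 1 and death at 0; the model
is explicit that these are *relative* weights - the comparison between arms is
meaningful even though absolute utilities in real patients would differ.

Each arm of the tree unfolds as: periprocedural complication (yes/no) ->
BNI outcome (four states) -> for initial failures (BNI IV-V), possible
re-treatment; for initial successes, possible recurrence with possible
re-treatment. Coexisting outcomes combine multiplicatively: a medicated BNI
III patient with a complication carries
`u(BNI III) x u(medication) x u(complication)`. A QALY timeline integrates
the piecewise-constant utility over the horizon, so four years at utility
0.25 contributes one QALY.

## Parameters

All inputs live in `treatment_params` objects and ship as a CSV
(`packaged_parameters_path()`); probabilities printed as percentages in the
source tables are converted to proportions exactly once, at the I/O boundary.
The base-case values:

```{r params}
params <- load_parameters(packaged_parameters_path())
sapply(params$MVD$bni_dist, function(e) e$mean)
sapply(params$SRS$bni_dist, function(e) e$mean)
c(MVD = params$MVD$recurrence_rate_7y$mean,
  SRS = params$SRS$recurrence_rate_7y$mean)
```

Three utility sub-trees feed the state utilities:

* **Complications.** Itemized incidences are assumed additive; the total is
  13.3% for MVD and 19.3% for SRS, and conditional on any complication the
  expected utility multiplier is the incidence-weighted mean of the entry
  utilities. Corneal keratitis after SRS compounds with facial numbness and
  facial palsy (those patients are assumed to carry trigeminal and facial
  nerve deficits too), so its terminal utility is the product of the three.
  Residual "other" categories have no published utility and carry 1.0 by
  default (an exposed override): with that choice the SRS sub-tree reproduces
  the published 0.962 exactly, while the MVD sub-tree evaluates to 0.953
  against a published 0.958 - the residual discrepancy is in the source's own
  arithmetic, and we report the computed value.
* **Medication.** Three side-effect severities whose printed probabilities sum
  to 1.001; we renormalize by the sum rather than truncating a category,
  preserving relative weights. The weighted mean is 0.874; the source prints
  0.881 for the same sub-tree. `medication_submodel()` returns the computed
  mean and accepts `pinned = 0.881` for users who prefer the printed constant.
* **Re-treatment.** Every procedure after the first multiplies subsequent
  utility by 0.915, compounding with depth, and at most two additional
  procedures are allowed.

One paper-internal conflict is worth stating: the pooled outcome table gives
the MVD complication rate as 17.6% (with the dispersion the PSA needs), while
the itemized MVD profile sums to 13.3%. The tree's complication *branch
probability* uses the pooled 17.6%; the itemized profile supplies only the
conditional utility multiplier. Both numbers are exposed in the parameter
object. The MVD BNI IV-V standard deviation (0.67%) is anomalously small next
to its neighbours but is transcribed verbatim.

## Event timing

Events are placed deterministically on the timeline, in months on the
parameter side and years internally:

| constant | MVD | SRS | meaning |
|---|---|---|---|
| response delay | 0 | 1 | months at the pre-treatment state (BNI IV-V, medicated) before the outcome applies |
| re-treatment delay | 1 | 3 | months before an initial failure is re-treated |
| complication onset | 0 | 6 | months until a (permanent) complication's utility multiplier starts |

Recurrence is assumed to happen 2.5 years after the procedure that produced
the state, in BNI IV-V while awaiting any re-treatment; untreated recurrences
settle at medicated BNI III for the remainder. The source states both "2.5
years" and "midway in the follow-up period"; we default to 2.5 years
(`recurrence_time_years`), which also makes the one-year horizon analysis a
pure short-term comparison (no recurrence can occur before one year). The
fraction of recurrences re-treated (8.0% MVD, 45.5% SRS) is also applied to
initial BNI IV-V failures, since the source gives a single figure; this
shared-fraction assumption is a deliberate, configurable choice. Re-treatment
modality follows the reported mix: failed MVD is followed by MVD in 80% of
cases (else SRS), failed SRS by MVD. BNI II carries no medication multiplier -
by the scale's own definition it is "not requiring medication" - though the
source never says so explicitly.

Perioperative death zeroes utility from onset to the horizon rather than
invoking a survival model; the QALY arithmetic in the source contains none,
and the death incidence (0.2% after MVD) is too small for the distinction to
matter at this horizon.

## Rollback, enumeration and microsimulation

`rollback()` is the standard leaves-to-root expectation. Its independent
oracle is `enumerate_paths()`, which lists every root-to-terminal path with
its product probability; the test suite checks the two agree to 1e-12 on
randomized trees and on the assembled treatment trees (about 2,300 paths at
the default configuration). Branch probabilities within 1e-6 of summing to
one are silently renormalized (printed tables carry rounding); larger
deviations are validation errors. Trees are immutable value structures and
evaluation is pure, so probabilistic-sensitivity draws cannot interact.

```{r rollback}
c(MVD = expected_qalys("MVD"), SRS = expected_qalys("SRS"))
```

## Probabilistic sensitivity analysis

Parameter uncertainty uses beta distributions for every probability and
utility, fitted by the method of moments; a zero standard deviation is a
point mass, and an infeasible one (sd^2 >= mean(1-mean)) is clipped to 95% of
the feasible bound with a warning. The two-dimensional Monte Carlo runs 100
outer trials - one independent draw of every parameter per trial, with the
four BNI probabilities renormalized after drawing (a Dirichlet would be the
alternative; independent-beta-then-renormalize is the simplest scheme
consistent with "beta for every probability") - and 100 inner patient
microsimulations per trial, each walking the assembled tree by sequential
categorical draws. Trial means are compared across arms by Welch's t-test at
the 0.05 two-sided level. The across-trial spread reported alongside the
grand means is the across-trial standard deviation. A single master seed
drives per-trial substreams, so results are bitwise reproducible and
independent of how trials might be scheduled.

## The meta-analytic layer

The pooled inputs are study-level proportions combined by inverse-variance
random-effects pooling on the raw-proportion scale (the stated method is
"inverse variance-weighted means"); logit-scale pooling is available as an
option for boundary-adjacent rates. Between-study variance uses the
DerSimonian-Laird moment estimator truncated at zero - the standard
random-effects model of the era, since no estimator is named - and Cochran's
Q with fixed-effect weights supplies the heterogeneity test. Proportions at 0
or n receive a 0.5 continuity correction. Studies in which more than 35% of
cases had a previous procedure are excluded at load, mirroring the stated
inclusion rule. Meta-regression (one covariate, DL weights, normal slope
test) reports R^2 as the fraction of between-study variance explained,
`(tau2_null - tau2_model)/tau2_null` truncated to [0, 1] - the conventional
definition, since the source reports R^2 without defining it. The published
near-unity R^2 (0.99) for the age-success association cannot be audited
without the per-study data and is reproduced only qualitatively.

## The synthetic corpus

No study-level dataset accompanies the pooled tables, so `generate_corpus()`
emulates the 57-publication evidence base: 17 MVD and 40 SRS studies (the
real split, with the three dual-arm publications counted on the SRS side),
sizes uniform on 15-500 (spanning the real corpus apart from two
registry-scale outliers; the exact size list ships as
`inst/extdata/corpus_study_sizes.csv`), follow-up normal with the reported
means/SDs (31.7 +/- 19.2 months SRS, 43.2 +/- 27.6 MVD) truncated below at 6
months, demographics from the reported distributions, and binomial event
counts at the pooled rates, optionally shifted on the logit scale by
covariate effects so regressions can be tested against known truth.

What the generator does *not* emulate - and hence what passing tests cannot
show about real data: publication bias and selective outcome reporting,
heterogeneous outcome definitions across studies, correlation between
outcomes within a study, and overdispersion beyond binomial sampling. The
generator's corpora are exactly as clean as the pooling model assumes; real
literature is not.

## Numerical choices and problem sizes

Probability renormalization tolerance 1e-6; rollback/enumeration agreement
asserted at 1e-12; beta moment round-trips at 1e-9; timeline assembly treats
segments shorter than 1e-12 years as empty. The test suite sizes were chosen
to keep Monte Carlo assertions at 3-sigma margins: 100,000 patients for the
microsimulation-vs-rollback check, 500 replicates for pooled-proportion
coverage, 100 replicates each for slope-sign recovery and for
corpus-to-QALY error propagation, and the full 100 x 100 PSA for the headline
comparison.

## Interface

This package is organised as an analysis: the numbered scripts under
`analysis/` run the pipeline (parameters, sub-trees, rollback and one-way
sensitivity, PSA, synthetic meta-analysis) and write their tables under
`results/`, while every computation lives in package functions so the tests
and `scripts/acceptance.R` exercise the same code paths. There is no shell
wrapper beyond these scripts; the functions are the API.

## Known limitations

The model inherits the source analysis's simplifications: permanent
complications only, a single aggregate complication multiplier per procedure
rather than per-complication timelines, one fixed recurrence time, no
discounting, no cost layer, no survival model, and no distinction among SRS
platforms. The PSA draws all parameters independently; real pooled estimates
are correlated (for example the four BNI proportions), so the across-trial
spread here is, if anything, conservative (wider than correlated draws would
give).
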