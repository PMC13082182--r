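---
title: "Heart-rate phase: model, pipeline and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Heart-rate phase: model, pipeline and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hrphase)
library(dplyr)
```

## The measure

Daily heart rate is rhythmic, and the timing of that rhythm tracks an
individual's circadian phase. `hrphase` quantifies this timing as the
**heart-rate phase (HRP)**: longitudinal wearable heart-rate samples are
averaged into a weekly profile of 5-minute bins (2016 bins for a full week,
288 per day), and the profile is fit to a sine curve with a fixed 24 h
(1440 min) period,

$$HR(t) = A \sin\!\left(\frac{\pi}{720}(t - \varphi_{min})\right) + b,$$

with $t$ in minutes, amplitude $A$, vertical shift $b$ and phase
$\varphi = \varphi_{min}/60$ reported in hours. Because the model is linear
in $(A\cos, A\sin, b)$, the package fits it on the basis
$\{\sin(\pi t/720), \cos(\pi t/720), 1\}$ and converts to the canonical form
$A \ge 0$, $\varphi \in [0, 24)$; this is the exact global least-squares
optimum, and a property test verifies agreement with an iterative nonlinear
optimizer to $10^{-6}$. Under this convention $\varphi$ is the **ascending
mean-crossing time** and the heart-rate *peak* occurs at $\varphi + 6$ h —
worth stating explicitly because "acrophase" in the cosinor literature names
the peak time. Later $\varphi$ means a phase-delayed (evening-shifted)
rhythm.

Fitting uses the 2016-point *weekly* series rather than a collapsed
288-point daily profile, and bins are unweighted regardless of how many raw
samples each contains. The two choices only differ when bin occupancy is
unequal; the weekly unweighted series is the literal form of the profile
being modelled.

## Threshold selection and inclusion

Participants are retained when (1) they have heart-rate data on **more than
30** distinct calendar days, (2) the sine fit's $R^2$ strictly exceeds a
threshold, and (3) their phase lies within 3 SD of the cohort mean phase.
The $R^2$ threshold is chosen by a Youden-style index over a grid
$\{0.0, 0.1, \ldots, 0.9\}$: retention($\theta$) is the number of fits with
$R^2 > \theta$ divided by the number with $R^2 > 0$, and the index is
retention $+\ \theta - 1$. The maximizer is selected, ties breaking toward
the lowest threshold (retaining more participants). The default threshold
when no scan is run is 0.5.

Two deliberate readings in step (3): the mean and SD are *linear* statistics
in hours, computed once over the survivors of steps (1)–(2) without
iteration — a unimodal, continuous treatment of phase, not a circular one —
and a survivor SD of exactly 0 disables the rule (otherwise
$|\varphi - \bar\varphi| \ge 0$ would exclude everyone).

## Downstream associations

* **Genotype–phase scan.** Per SNV, alleles are counted over the genotyped
  population; the most frequent allele is the reference, the second the
  (effect) alternate, variants with alternate AF < 1% are excluded, and
  participants carrying any third allele are excluded from that SNV only.
  Phase (hours) is regressed on additive dosage plus age, Y-chromosome
  presence and five ancestry PCs by OLS with sandwich (HC1) standard errors;
  effects are reported in minutes per allele and Bonferroni-adjusted over
  the SNVs actually tested. HC1 is the default because only "robust"
  standard errors are specified by convention; HC0–HC3 are available.
* **Phenome-wide scan.** A participant is a case for a concept if they have
  an occurrence of the concept or of a descendant within **two** degrees of
  separation (shortest-path distance, so DAG-shaped vocabularies are
  handled); concepts with more than 100 cases are scanned by logistic
  regression (same covariates plus weekly steps), again with HC1 errors and
  Bonferroni control. Non-convergent or separated fits are flagged rather
  than dropped.
* **Disease-focused models.** The disease flag uses the *unlimited*-depth
  closure. HbA1c processing keeps values in [1, 30]%, takes each
  participant's maximum strictly *before* the monitoring end date
  (a conservative reading of "before"; date-equal measurements are
  excluded), and calls > 5.6% elevated; using the maximum guards against
  medication-lowered later values. Age at diagnosis is modelled by Cox
  regression on the age scale, stratified by Y-chromosome presence, with a
  scaled-Schoenfeld proportional-hazards check; there is no left truncation
  at monitoring start (delayed entry is not part of the specification — a
  known deviation risk noted here rather than silently patched). The
  "linearity of the log odds" visual check is replaced by a
  deciles-of-exposure empirical-logit table (`logit_linearity_table()`).
* **Mendelian randomization.** One-sample MR by two-stage residual
  inclusion: stage 1 regresses phase on the instrument dosage and exogenous
  covariates (instrument strength summarised by the Wald F and model
  $R^2$); stage 2 is a logistic regression of the outcome on the stage-1
  residual, phase and the exogenous covariates, the causal estimate being
  the phase coefficient and the residual coefficient serving as an
  endogeneity diagnostic. Confidence intervals are percentile intervals
  from a participant-level bootstrap that re-fits *both* stages per
  resample — the standard one-sample choice when only "bootstrapped CIs"
  are specified. Both the analytic Wald p and the bootstrap p are reported,
  since which one a headline p-value represents is ambiguous. F < 10
  triggers a weak-instrument warning but not a failure.

## The synthetic cohort

Controlled-access wearable/EHR data cannot ship with a package, so
`simulate_cohort()` generates all five input tables with the causal
structure the analysis assumes: binomial genotype dosages; true phase
$\varphi_i = \mu_\varphi + \sum_k d_{ik}\beta_k/60 + \gamma U_i +
\varepsilon_i$ with an unobserved standard-normal confounder $U_i$;
sinusoidal heart-rate samples at 5-min resolution with Gaussian noise and
independent per-sample missingness; logistic disease risk in phase, steps,
age and sex (plus $\gamma U_i$); and HbA1c linear in phase, clipped to
[1, 30]%.

Defaults mirror a large wearable cohort: phase 9.48 ± 1.57 h, steps
5.43 ± 2.49 (10,000/week), age 53 ± 16 truncated to [25, 85], 32.7% Y
chromosome, HR amplitude 10 ± 2 bpm over a 75 ± 8 bpm baseline (a typical
circadian heart-rate swing; the source cohort does not publish amplitude),
5 bpm sample noise, 20% missingness, a morningness variant at 2.5%
alternate AF shifting phase −30 min/allele, and a T2DM-like condition with
~13% prevalence, OR 1.09 per hour of phase and diagnosis-age log-HR 0.17
per hour. Monitoring spans default to 60 days — long enough for stable fits
at desk scale; real wearable spans (median near one year) only improve the
fit.

Two modelling choices were genuinely open:

* **Disease indicator vs diagnosis age.** Case status is drawn from the
  logistic model (so with null coefficients prevalence is exactly
  `plogis(intercept)`), and cases receive a diagnosis age of 20 years plus
  an exponential waiting time with rate
  `hazard_rate × exp(loghr_phase·(φ − μ) + γU)`; occurrences falling after
  the censoring age are unobserved. For clean Cox parameter-recovery the
  intercept can be set large (everyone susceptible) so that censoring alone
  produces the event fraction and the partial likelihood is exactly
  consistent for `loghr_phase`; mixing logistic susceptibility with timing
  makes the Cox estimand a blend, which is realistic but not a recovery
  target.
* **Confounding.** $U_i \sim N(0,1)$ enters both the phase and every
  outcome linear predictor with one shared coefficient — the minimal
  structure under which naive logistic regression is biased but a valid
  instrument is not, i.e. exactly what is needed to demonstrate the value
  of two-stage residual inclusion.

Timestamps are naive local wall-clock with no timezone or DST handling
(wearable exports are local time). What the generator does **not** emulate:
ultradian and activity-driven heart-rate microstructure, device-specific
noise, seasonal phase drift, correlated missingness (e.g. overnight
non-wear), and real vocabulary shapes. Passing recovery tests therefore
demonstrates correctness of the estimators under the assumed structure, not
robustness to real-world artefacts.

## Numerical and degenerate-input choices

* Sine fits need ≥ 3 bins at distinct times-of-day; constant profiles get
  $R^2 \equiv 0$ and a flag rather than an error.
* Allele ties (equal counts) break alphabetically so ref/alt assignment is
  deterministic.
* The threshold-scan tie-break is "lowest threshold", which also resolves
  the all-perfect-fits edge case to the top of the grid only when the index
  is strictly maximal there.
* Cohen's d uses the pooled-SD definition with a normal-approximation CI
  ($SE^2 = (n_1+n_2)/(n_1 n_2) + d^2/(2(n_1+n_2))$); zero variance in both
  groups flags the comparison (d defined as 0 only when the means agree).
* All randomness in a pipeline run derives from one seed via fixed
  per-stage offsets, so end-to-end manifests are reproducible
  byte-for-byte.
* Bootstrap replicates whose stage-2 fit fails to converge are dropped and
  counted (`n_dropped`), never silently imputed.

## Worked example

```{r example, eval = FALSE}
cfg <- sim_config(n_participants = 200, n_days = 45, seed = 1)
sim <- simulate_cohort(cfg)

fits <- extract_phases(sim$hr)
scan <- select_r2_threshold(fits)
cohort <- apply_inclusion_filters(fits, sim$covariates,
                                  threshold = selected_threshold(scan))

snvs <- compute_allele_frequencies(sim$genotypes)
assoc <- associate_snv_phase(dplyr::filter(cohort, included),
                             code_additive(sim$genotypes, snvs))
assoc

pipeline <- run_pipeline(sim, n_resamples = 1000, seed = 1)
pipeline$manifest$counts
glance(pipeline$mr)
```

## Problem sizes used in the test suite

The suite exercises the estimators at sizes chosen to make Monte-Carlo
tolerances meaningful while keeping a default test run quick: full-week
binning at 2016 bins; 100-profile optimizer-equivalence checks; 200
simulated participants (5 bpm noise, 20% missingness, 60 days) for phase
recovery; 100 replicates at n = 15,000 for logistic CI coverage; 100
replicates of 200 null concepts at n = 800 for family-wise error; n =
10,000 (~1,500 events) for Cox recovery; and for MR, 50 replicates at n =
15,000 for the bias comparison plus 200 replicates with 1,000 bootstrap
resamples at n = 1,000 for CI coverage (the headline method's default of
100,000 resamples is impractical to repeat hundreds of times, and 1,000
resamples already stabilises the percentile CI at these sample sizes).

## Known limitations

* Period is fixed at 1440 min; no multi-harmonic cosinor or period
  estimation.
* No circular statistics: the 3-SD rule and all regressions treat phase
  linearly, which is appropriate for unimodal morning-centred cohorts and
  wrong for phase distributions spanning midnight.
* The Cox model ignores delayed entry and competing risks; immortal-time
  effects for participants diagnosed before monitoring are inherited from
  the specification, not corrected.
* Single-instrument MR only; no pleiotropy sensitivity analyses
  (MR-Egger and friends are explicitly out of scope).
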