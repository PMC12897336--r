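---
title: "A decision-analytic cost-utility model for QoL-prediction-guided psychosocial support"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A decision-analytic cost-utility model for QoL-prediction-guided psychosocial support}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qolcea)
```

## The decision problem

Many women treated for early breast cancer experience a lasting loss of
quality of life (QoL), and individual psychosocial support (IPS) — a
cognitive-behavioural course of roughly five sessions over about six months —
can mitigate it. The difficulty is targeting: support helps only patients
whose QoL would truly be low a year after diagnosis, and identifying those
patients in routine care is hard. `qolcea` implements a decision-analytic
cost-utility model that compares four allocation strategies:

* **clinician** — the clinician predicts each patient's one-year QoL and
  offers IPS to those predicted low;
* **clinician_plus_predictor** — the clinician decides after seeing the
  output of a machine-learning QoL predictor;
* **predictor_only** — the predictor decides autonomously;
* **no_prediction** — no prediction is made and nobody receives IPS
  (standard care).

Each prediction strategy is characterised purely by its operating point — a
sensitivity and a specificity against the true one-year QoL state — plus a
per-patient prediction cost. The development of the machine-learning
predictor itself is out of scope here; its operating characteristics enter
as data.

## Model structure

Patients have a binary true state: *low QoL* with probability $p$
(prevalence), *high QoL* otherwise, fixed during the decision process. A
QoL utility score of 0.75 or less defines the low state. Over the one-year
horizon a low patient accrues $u_\text{low} = 0.63$ QALYs and a high patient
$u_\text{high} = 0.85$ (no discounting at one year). For a strategy $s$ with
sensitivity $\mathrm{se}_s$ and specificity $\mathrm{sp}_s$, the
predicted-low (treated) fraction is

$$\Pr(\text{pred low}) = p\,\mathrm{se}_s + (1-p)(1-\mathrm{sp}_s),$$

and only *treated true positives* — probability $p\,\mathrm{se}_s$ — benefit
from IPS. False positives incur the full course cost with no health gain, a
deliberately conservative assumption that keeps the model aligned with the
user experiment the operating points come from. The no-prediction strategy
is a degenerate classifier (sensitivity 0, specificity 1, zero cost), so all
four strategies flow through the same engine.

Expected QALYs are

$$E[Q_s] = p\,u_\text{low} + (1-p)\,u_\text{high}
          + p\,\mathrm{se}_s \cdot \Delta u \cdot f,$$

where $\Delta u = 0.08$ is the IPS utility gain and $f$ the fraction of the
year over which it accrues. Expected cost sums the prediction cost, the IPS
course cost for every predicted-low patient, expected healthcare-visit
costs, and — under the societal perspective — sick-leave days valued by the
human-capital method. Visits and sick-leave days decline with QoL: treated
true positives avoid `visit_coeff` visits and `sickday_coeff` days per
+0.01 QoL gained (base case 0.2 and 1.2, i.e. 1.6 visits and 9.6 days for
the +0.08 gain). Restricting the utilization reductions to treated true
positives mirrors the QALY rule; letting false positives "save" utilization
would contradict the assumption that only truly low-QoL patients benefit.
Strategies are compared by net monetary benefit,
$\mathrm{NMB} = \lambda\,E[Q] - E[C]$ at $\lambda$ = EUR 30,000/QALY, and by
the incremental cost-effectiveness ratio along the cost-ordered frontier.

```{r basecase}
params <- default_parameters()
evaluate_all(params)[, c("strategy_id", "expected_cost", "expected_qaly", "nmb")]
```

## Calibration: the two parameters the source does not print

**Prevalence.** The published analysis estimated $p$ from cohort data it
does not reproduce, but it prints the untreated cohort's expected QALYs,
0.745, which under the two-state model equals the mixture mean
$p\,u_\text{low} + (1-p)\,u_\text{high}$. `calibrate_prevalence()` inverts
this: $p = (0.85 - 0.745)/(0.85 - 0.63) = 0.4773$. The synthetic-cohort
generator uses the same value as its default true prevalence so every stage
of the pipeline is mutually consistent.

**Benefit accrual.** The IPS course spans roughly six months, and
`benefit_duration_fraction` defaults to 0.5: half-year accrual of the +0.08
gain (0.04 QALYs per treated true positive) is the unique convention that,
with the calibrated prevalence, reproduces the published incremental QALYs
of 0.013 / 0.014 / 0.011 to their printed rounding. Full-year accrual is a
single configuration change away for users who prefer it.

```{r calibration}
calibrate_prevalence(0.63, 0.85, 0.745)
verify_calibration()
```

**Patient fees.** The published "third-payer" costs are reproduced most
closely when patient co-payments are included in the unit costs (EUR 1011
per IPS course, EUR 367 per visit); under that convention, the default,
modeled absolute costs sit within 3% and NMBs within 1% of the published
table. The wording of the source leaves the convention ambiguous, so
`include_patient_fees` is explicit configuration, not a claim about what the
original spreadsheet did. Exact reproduction of the published absolute
costs and of its incremental costs (316/310/250 EUR) is not attainable from
the printed text under any single convention we tested; the dominance
structure and incremental QALYs are reproduced exactly.

**Compliance.** The source mentions compliance parameters from the user
experiment but prints none; the model fixes compliance at 1 rather than
guessing a value.

## Incremental analysis

`build_frontier()` orders strategies by increasing cost (ties broken by
higher QALYs), marks strict dominance (cost $\le$ and QALYs $\ge$ with at
least one strict), then iteratively removes extended dominance — an ICER
versus the previous frontier member that *strictly* exceeds the ICER of the
next, more effective member. Equal ICERs (collinear strategies) are kept;
this boundary choice is verified against an exhaustive enumeration oracle
(a strategy is on the frontier iff it maximises NMB for some
$\lambda \ge 0$). Because the source reports ICERs both against the
previous cost-ordered strategy and against the reference, the incremental
table carries both columns.

```{r frontier}
build_frontier(basecase_reference())
```

On the published table this reproduces the printed labels: the
clinician-only strategy is strictly dominated, the predictor-alone strategy
extendedly dominated, and only the combined strategy remains on the frontier
beyond the no-prediction reference.

## The synthetic cohort generator

No patient-level data from the source study are public, so
`generate_cohort()` emulates the structure the model assumes and is itself
first-class, tested code:

* **True state** — Bernoulli($p$), default the calibrated 0.4773.
* **12-month utility** — truncated normal within the state's interval
  (low: $(0, 0.75]$, high: $(0.75, 1]$), default spread 0.08. The location
  is solved numerically so the *truncated* mean equals the configured group
  mean; naive truncation at the group mean would bias both groups by about
  0.01 and break parameter recovery. This keeps the threshold/state
  consistency exact by construction.
* **Utilization** — annual visit and sick-day counts with mean
  $a + b\,u_{12m}$ (floored at zero). `count_noise` is the variance-to-mean
  ratio: 0 gives deterministic rounded means (useful for exactness tests),
  1 Poisson, and values above 1 a negative binomial; the default 1.5 adds
  the mild overdispersion typical of visit counts.
* **Determinism** — one integer seed governs every stream; identical seeds
  give byte-identical cohorts.

The default utilization lines pass through the published group means (19/15
visits and 130/86 sick-leave days at utilities 0.63/0.85), i.e. slopes of
−18.2 visits and −200 days per unit QoL. Note that the published *reduction
coefficients* (0.2 visits and 1.2 days per +0.01 QoL) are not consistent
with the sick-leave group means — a 0.22-utility gap would imply ~26 days,
not 44 — because they come from different sources. The generator reproduces
the group means; the decision model consumes the coefficients; both are
configurable.

`estimate_prevalence()`, `summarize_cohort()` and `fit_utilization_slope()`
(ordinary least squares from the closed-form normal equations, cross-checked
against `lm()` in the test suite) recover the generating parameters, so the
cohort also serves as the microsimulation oracle: `microsim_strategy()`
replays the decision tree patient by patient and agrees with the analytic
expectations within Monte Carlo error.

What the generator does *not* emulate: the real cohort's covariates, its
three-month assessment wave, within-patient correlation between visits and
sick leave beyond their shared dependence on utility, and any non-normal
shape of the utility distribution. Passing tests therefore demonstrate
internal consistency of the model chain, not external validity on real
patients.

## Probabilistic sensitivity analysis

`run_psa()` samples the uncertain parameters per draw — gamma for costs
(method of moments: shape $= 1/\mathrm{CV}^2$), beta for the utility-scale
IPS gain, normal for the two regression coefficients, with the state
utilities, group utilization levels and the sick-day unit cost held fixed —
then evaluates all four strategies once per draw; costs and QALYs do not
depend on $\lambda$, so one draw serves the whole willingness-to-pay grid
(EUR 1, then 1,000-EUR steps to 140,000). `ceac()` converts the draws into
acceptability curves; exact NMB ties are split equally, which matters only
in the degenerate all-fixed mode where the curves must be exact {0,1} step
functions.

The source states the distribution families and that "wide confidence
intervals" were used, but not the spreads. The defaults — CV 0.2 for gamma
costs, sd 0.02 for the beta-distributed +0.08 gain, sd equal to half the
mean for the normal coefficients — are this package's own choice and are
flagged as such; reproducing the published 69%/31% acceptability figures is
therefore not claimed, only the structural properties (normalization,
limiting behaviour, seed reproducibility, stability in the number of
draws). Normal coefficient draws are not truncated at zero: a negative draw
means treatment increases utilization, which is genuine sign uncertainty;
the engine clamps expected utilization at zero (with a warning) only if a
parameter combination would drive it negative.

```{r psa, eval = FALSE}
psa <- run_psa(params, n_sims = 10000, seed = 1)
curves <- ceac(psa)
plot_ceac(curves)
```

## Numerical conventions and problem sizes

* Monetary values are plain doubles in 2024 EUR; report views round costs to
  whole euros and QALYs to three decimals, matching the published tables;
  machine outputs keep full precision.
* Cohort CSVs are written with 17 significant digits so round trips are
  bit-exact.
* The truncated-normal location solve uses `uniroot` at tolerance 1e-12.
* Validation errors always name the offending field.
* The test suite exercises the microsimulation oracle at 200,000 patients,
  parameter recovery at 100,000, the frontier-versus-enumeration property on
  1,000 random strategy sets, and PSA reproducibility at 10,000 draws —
  sizes chosen to make three-standard-error checks sharp while keeping the
  suite fast.

## Limitations

The model inherits the source analysis's structure: a static one-year
decision tree with a dichotomous QoL outcome, benefit restricted to treated
true positives, conditionally independent predictions, and no repeat
decision points or utility trajectories (a Markov or discrete-event
extension is explicitly out of scope). Absolute costs depend on a
fee-inclusion convention the source leaves ambiguous, and the PSA spreads
are package defaults, not published values; conclusions that depend on
either should be read as sensitivity analyses, with the configuration
mechanism provided for exploring alternatives.
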