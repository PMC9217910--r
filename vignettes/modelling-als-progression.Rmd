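---
title: "Modelling ALS progression with constrained two-slice dynamic Bayesian networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling ALS progression with constrained two-slice dynamic Bayesian networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alsdbn)
```

## The model

ALS registries record one row per clinic visit: demographics fixed at
diagnosis, ALSFRS-R functional scores, support interventions, and a
survival outcome (tracheostomy/death or censoring). Visits are irregular
— roughly every 3.5 months on average, more frequent as the disease
advances — and values are missing throughout.

`alsdbn` represents a patient as a sequence of discrete states and
models the transition between consecutive visits with a **two-slice
dynamic Bayesian network**. Variables fall into four roles:

* *static* (sex, onset site, age at onset, diagnostic delay, centre, and
  in the advanced scenario genetics, familial ALS, FTD, BMI, FVC): fixed
  over time, allowed to depend only on other statics (a small
  contemporaneous DAG, e.g. onset site may depend on sex);
* *dynamic* (the four MiToS domain flags; NIV and PEG in the advanced
  scenario): at visit $t$ each has a conditional probability table given
  parents at visit $t-1$ — never given other slice-$t$ variables, so
  one visit-to-visit transition factorizes completely;
* *derived-temporal*: TBV, the gap in months to the previous visit, and
  TSO, months since symptom onset. TBV at $t$ is itself sampled from a
  learned table (the model learns how visit frequency evolves); TSO
  advances deterministically, $\mathrm{TSO}(t) = \mathrm{TSO}(t-1) +
  \mathrm{TBV}(t)$, and is re-discretized for conditioning — the only
  reading consistent with TSO being the running sum of the gaps;
* *outcome*: a binary alive/dead survival node, absorbing. Death is
  injected into the transition data as a terminal pseudo-visit at the
  survival time (all other slice-$t$ values missing), so the data
  contain alive-to-dead examples and "the simulated death ends the
  simulation" is well defined. Because every observed transition starts
  from an alive state, survival is never offered as a parent.

MiToS staging derives the four domain flags from ALSFRS-R items
(walking/self-care lost if walking ≤ 1 OR dressing/hygiene ≤ 1;
swallowing if its item ≤ 1; communication if speech ≤ 1 AND handwriting
≤ 1; breathing if dyspnoea ≤ 1 OR respiratory insufficiency ≤ 2). The
table ships as configuration, not code; a missing required item yields a
missing flag unless the observed items already decide it under the
AND/OR rule. Missing flags are propagated, never imputed.

Continuous variables are discretized at their training-set quantiles
(type-7 linear interpolation, right-closed intervals: a value equal to a
cut falls in the lower bin; both conventions are recorded in the
serialized schema). Three levels per variable is the default. The first
visit has no predecessor, so its TBV takes a distinguished `"baseline"`
level rather than being dropped — baseline rows must remain usable as
simulation start states.

## Learning

Structure search is Max–Min Hill-Climbing: an MMPC screening phase
(G² conditional-independence tests, default α = 0.05, conditioning sets
up to size 3) proposes candidate parents per child, then a greedy
add/delete search maximizes the family BIC
$\log \hat L - \tfrac12 \log(N)\, q\,(r-1)$ within the candidates. All
scores and tests use **available cases**: each family is evaluated on the
rows where the child and all its parents are observed, so missing data
never require imputation. Inter-slice families are optimized
independently (valid because slice-$t$ children share no edges); the
static layer is a joint greedy search with acyclicity checks. Ties break
lexicographically, so learning is fully deterministic.

Domain knowledge enters as constraints: edges into exogenous
demographics (sex, age at onset, centre) are forbidden, and the MiToS
flags and survival are mandated to depend on TSO, encoding the
progressive nature of the disease. Mandatory edges are never removed,
forbidden edges never added, and every returned structure is re-checked
against the constraint set. Self-loops $X(t-1) \to X(t)$ are allowed but
not forced.

Parameters are MAP estimates under a uniform Dirichlet prior of total
mass `ess` (default 1) spread over each table:
$p = (n_{ijk} + \mathrm{ess}/\mathrm{cells}) / (n_{ij} +
\mathrm{ess}\,r/\mathrm{cells})$. Unseen parent configurations therefore
yield a uniform row, and `ess → 0` recovers maximum likelihood.
Bootstrap edge confidence resamples patients with replacement (default
100 samples), relearns the structure each time, and reports per-edge
occurrence counts (a WPDAG).

## Simulation

From one complete baseline visit (completeness is required; the package
deliberately offers no baseline imputation), each repetition advances
step by step: sample the TBV bin from its table, convert it to
continuous months by drawing from the training values that fell in that
bin ("bin-empirical"; "bin-uniform" draws within the bin bounds when no
pool exists), accumulate TSO, then sample every dynamic and outcome
variable given the slice-$(t-1)$ values. Defaults are 100 repetitions of
at most 40 steps, a horizon that covers the typical follow-up and lets
the survival endpoint be reached; death ends a repetition. Event times
are first occurrences (learned tables may allow rare impairment
reversals; the flags are monotone-tending, not hard-absorbing), and a
domain already impaired at baseline has its event at the baseline TSO.

Each patient draws from an own random stream derived from the master
seed and the patient id, so results are bit-reproducible and independent
of cohort ordering.

## Evaluation

Discrimination uses the cumulative/dynamic time-dependent AU-ROC on a
3-month grid from month 6 to 96 after onset: at time $\tau$ a patient's
risk score is the fraction of repetitions with the event by $\tau$;
cases are patients with an observed event by $\tau$, controls those
event-free and still under observation, and patients censored before
$\tau$ are excluded (a flag switches to the treat-as-controls
convention). Grid times with no cases or no controls are reported as
undefined and skipped — the first grid point usually is. The integrated
AU-ROC is the trapezoidal integral over the defined grid up to a horizon
(24, 36, 96 months) divided by the integrated span: a time-averaged
AU-ROC in $[0,1]$, which is the only reading consistent with reported
magnitudes.

Calibration compares the observed cumulative incidence with the
repetition-mean simulated curve (spread = across-repetition SD), and a
χ² statistic over the eight time slices
$[0,6], (6,9], (9,12], (12,18], (18,24], (24,30], (30,36], (36,96]$
months, with expected counts from the repetition-averaged simulated
events scaled to the cohort size (a pooled-repetitions variant is
available; the two coincide in expectation). Slices with zero expected
and positive observed counts merge upward. Note that right-censoring
depresses *observed* counts in late slices while the simulation keeps
producing events, so on heavily censored cohorts the raw-count χ² is
conservative against the model; the self-consistency tests therefore use
fully observed synthetic cohorts when checking the test's type-I
behaviour.

## The synthetic generator

Because the clinical registries behind this class of models are not
publicly deposited, the package ships a ground-truth generator whose
defaults emulate their published summary shape: log-normal inter-visit
gaps with mean ≈ 3.5 months, first visits at a median ≈ 10 months after
onset, 3–6 recorded visits per patient (visit cap 15), ≈ 20%
administrative censoring, ≈ 75–80% deceased, and MCAR missingness
(default 3% per cell; an optional stress rate for the available-cases
machinery). Impairment hazards rise with TSO and are modified by
clinically established factors: bulbar onset accelerates swallowing
(×2.5) and communication (×2) impairment; impaired walking accelerates
communication impairment; the death hazard carries respiratory
impairment (×2.5), older age at onset (×1.9; young ×0.55) and bulbar
onset (×1.5). Without the static prognostic effects on survival, a
baseline visit would carry almost no survival signal and even the
Bayes-optimal discriminator would hover near chance — unlike the
registries being emulated, where survival is strongly predictable from
baseline. Once impaired, a domain persists with probability 0.97
(monotone-tending, like the staging it emulates); the death hazard is
capped at 0.97 per step so no state is a guaranteed one-step killer.

What the generator does **not** emulate: correlated missingness
patterns, centre effects on data quality, measurement error in ALSFRS-R
scoring, competing non-ALS mortality, and informative censoring. Tests
passing on these cohorts therefore demonstrate correctness of the
machinery and identifiability under the stated conditions, not clinical
performance on real registry data.

A sharp variant (`recovery_spec()`, 8 variables, every transition-table
row ≥ 0.9 on its dominant entry) is used for structure- and
parameter-recovery experiments; under it MMHC recovers the generating
structure essentially exactly from 3000-patient cohorts.

## Numerical and design choices

* Quantile cuts are refit on the training side only and frozen into the
  schema; models serialize to JSON with 17 significant digits, which
  round-trips doubles exactly.
* BIC penalty counts $q\,(r-1)$ free parameters over *all* parent
  configurations, observed or not (the standard convention).
* G² degrees of freedom use the declared level cardinalities.
* Hill-climbing accepts a move only if it improves BIC by more than
  1e-9; tie-break is lexicographic.
* The balanced split draws `n_attempts` (default 50) candidate splits
  and keeps the one maximizing the minimum balance p-value across
  baseline variables and the outcome — a posteriori balance checking,
  not stratified randomization.
* Event-time densities in stratification use 1-month histogram bins with
  the earliest-argmax rule for the mode (modes are reported in integer
  months); a Gaussian kernel overlay is available for plotting only.
* Degenerate inputs fail loudly: duplicate visit times, negative TSO,
  all-identical values offered for discretization, incomplete simulation
  baselines, constraints forcing a static cycle.

Experiment sizes used by the shipped validation suite (chosen as the
smallest cohorts at which the corresponding properties are stably
identifiable): structure recovery on 3000-patient sharp cohorts over 10
seeds; parameter recovery at 200 / 2000 / 20000 transitions; closure on
a 2000-patient training and 400-patient test cohort at the full 100 × 40
simulation protocol, with the calibration type-I check over 100 seeds of
120 fully observed patients; stratification direction on 600-patient
cohorts with a 6-level TSO ramp (a smoothly rising hazard gives the
event-time density a real interior peak; with the default 3-level step
hazard the mode pins at the first hazard jump in both strata and the
comparison degenerates).

## Limitations

* MMHC is a heuristic; it can return a local optimum. Bootstrap edge
  confidence is the supported way to judge structural stability.
* Available-cases scoring compares families on different effective
  sample sizes; with heavy, non-MCAR missingness this can bias the
  search. The package intentionally mirrors the no-imputation design
  rather than correcting for it.
* The cumulative/dynamic AU-ROC treats censoring by exclusion; no
  inverse-probability weighting is applied, and no confidence intervals
  are reported for AU-ROC values.
* Competing risks are not modelled: death censors the impairment
  outcomes in both the observed labels and the simulation, consistently
  but naively.
* Calendar-date ETL is out of scope: visit times must already be
  expressed as months since symptom onset.
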