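---
title: "Methods: a partitioned-survival cost-effectiveness model for second-line HR+/HER2- metastatic breast cancer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: partitioned-survival cost-effectiveness modelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psmcea)
```

## The decision problem

`psmcea` implements a decision-analytic model comparing everolimus plus
exemestane (EVE+EXE) against bevacizumab plus paclitaxel (BEV+PACL) and
bevacizumab plus capecitabine (BEV+CAPE) as second-line treatment for
postmenopausal women with hormone-receptor-positive, HER2-negative
metastatic breast cancer, from a third-party-payer perspective. The model
produces, per arm, lifetime discounted costs, quality-adjusted life years
(QALYs) and life years (LYs), and compares arms by incremental
cost-effectiveness ratios (ICERs) and dominance.

## Model structure

The disease course is represented by three mutually exclusive health
states — *pre-progression*, *post-progression* and *death* (absorbing) —
on a monthly cycle. We use the partitioned-survival construction: state
occupancy is read directly off the progression-free-survival (PFS) and
overall-survival (OS) curves rather than from an explicit transition
matrix,

$$
\text{pre}(t) = S_{\mathrm{PFS}}(t),\qquad
\text{dead}(t) = 1 - S_{\mathrm{OS}}(t),\qquad
\text{post}(t) = S_{\mathrm{OS}}(t) - S_{\mathrm{PFS}}(t).
$$

This is the standard construction when the evidence base consists of
survival curves plus hazard ratios, and it reproduces the three-state
structure exactly. The cohort enters fully pre-progression at cycle 0;
cycle $t$ covers the interval $(t-1, t]$ months, with events attributed to
the end of their cycle. New deaths in cycle $t$ are
$S_{\mathrm{OS}}(t-1) - S_{\mathrm{OS}}(t)$.

The default horizon is 180 months (15 years). With the survival inputs of
the packaged base case, residual survivorship at the horizon is below
0.1%; any run leaving more than that emits a truncation warning, so a
"lifetime" claim is always checked rather than assumed.

## Survival extrapolation

Trial follow-up is shorter than the model horizon, so PFS and OS are
extrapolated with parametric families: exponential, Weibull, Gompertz and
log-logistic, with the closed-form survival functions documented in
`?parametric_survival`. Fits to (pseudo) individual-patient data are
maximum-likelihood under right censoring via `flexsurv`, and the best
family is chosen by minimum AIC (`select_best_fit()`), with ties broken by
parsimony and then a fixed family order so selection is deterministic. The
Weibull is the base-case family.

Two practical restrictions:

* **Gompertz shape must be positive.** A non-positive shape implies a
  plateau (cure fraction), which is incompatible with a lifetime horizon in
  metastatic disease; such fits are rejected with an explanatory error
  rather than silently extrapolated.
* **Exponential "endpoint" vs "curve" modes.** The exponential family can
  be fitted to the full follow-up by maximum likelihood
  (`fit_parametric(..., "exponential")`) or solved from a single landmark
  survival probability (`exponential_endpoint()`). Both reduce to the same
  one-parameter family; they are exposed as alternative fitting modes.

Comparator efficacy enters through **hazard-ratio chains**
(`hr_chain()`): in the absence of head-to-head trials, published hazard
ratios are chained multiplicatively (an indirect comparison) and applied
as a proportional-hazards transform $S_{\text{new}}(t) =
S_{\text{base}}(t)^{\mathrm{HR}}$. Exponential, Weibull and Gompertz are
closed under this transform and are returned in-family; the log-logistic
is returned as a generic power-transformed curve.

Because PFS and OS receive independent hazard-ratio chains, the
transformed curves can cross. Progression precedes or coincides with
death, so the pipeline clamps point-wise
$S_{\mathrm{PFS}}(t) \leftarrow \min(S_{\mathrm{PFS}}(t),
S_{\mathrm{OS}}(t))$ before the trace is built; the trace itself refuses
inconsistent inputs.

## Discounting

Costs and outcomes are discounted at 3.5% per year by default. Two
conventions are implemented because published models are often ambiguous
between them:

* **"Beyond one year" step discounting** (default): cycles 1–12 carry
  factor 1; thereafter the factor steps annually,
  $(1+r)^{-\lfloor t/12 \rfloor}$.
* **Continuous monthly discounting from entry** (`discount_from_start`):
  $(1+r)^{-t/12}$, the more common textbook convention.

Neither is claimed to be "the" published choice; both are tested, and a
zero rate makes discounted and undiscounted totals identical in either
mode.

## Costing and QALY accrual

Costs accrue over the trace in five components mirroring the published
results-table rows, so regression comparisons can be made row by row:

1. **Treatment and administration**: pre-progression occupancy times drug
   acquisition (optionally scaled by relative dose intensity) plus
   administration cost.
2. **Adverse events**: grade 3/4 events enter as one-off expected costs
   $\sum_k f_k c_k$ and QALY decrements $\sum_k f_k d_k$ at model entry,
   undiscounted. The timing choice is the simplest reading of a one-off
   cost and is numerically immaterial at the published magnitudes
   (≤ 62 €).
3. **Pre-progression background**: pretreatment, laboratory, monitoring
   and prophylaxis costs per cycle.
4. **Post-progression background**: an aggregate monthly cost. Where the
   aggregate must be built up, `post_progression_cycle_cost()` implements
   the duration-weighted mean over treatment lines within each
   post-progression strategy and the share-weighted mean across strategies
   (the packaged base case uses the published aggregate directly).
5. **Terminal care**: a one-off end-of-life cost attached to the cycle of
   death via the new-deaths column, discounted at that cycle — this
   reproduces the pattern that a fixed end-of-life input appears in
   discounted results slightly below its nominal value.

Relative dose intensity (RDI) multiplies the drug-acquisition component
only: a reduced dose reduces drug consumed, not infusion visits or
monitoring. The EVE+EXE arm carries a single blended RDI because the
published combined acquisition cost is not split by component; the blend
(0.87) is weighted towards everolimus, which dominates the combined cost.

Utilities are annual weights applied to occupancy:
per-cycle QALYs are $(\text{pre}\cdot u_{\text{pre}} +
\text{post}\cdot u_{\text{post}})/12$, with $u_{\text{pre}} = 0.7733$ and
$u_{\text{post}} = 0.4964$ in the base case. The package enforces
$0 \le u_{\text{post}} \le u_{\text{pre}} \le 1$: configurations with a
post-progression utility above the pre-progression one are rejected, which
also bounds the admissible range of one-way sensitivity analyses on
$u_{\text{pre}}$ from below by $u_{\text{post}}$.

Half-cycle correction is off by default and available as a flag; when on,
each cycle's occupancy is the average of its start and end values
(equivalently, trapezoid integration of the survival curves).

## Incremental analysis

`incremental()` computes $\Delta C$ and $\Delta E$ (QALYs or LYs,
discounted), classifies the cost-effectiveness-plane quadrant and labels
the comparison. Dominance is strict: *dominant* means cheaper **and** more
effective; *dominated* the reverse. In the northeast quadrant the ICER
$\Delta C / \Delta E$ is compared with the willingness-to-pay threshold
(36,000 €/QALY by default, anchored to about twice the national GDP per
capita). The southwest quadrant — cheaper but less effective, which is how
the EVE+EXE comparison comes out on the life-year scale — is labelled
`less_effective_and_cheaper` and still reports the ICER, interpretable as
savings per unit of effect forgone; discarding it would lose information
the plane contains. Net monetary benefit ($\mathrm{NMB} = \lambda E - C$)
is provided and is property-tested to agree with the ICER rule wherever
both apply. On the axes ($\Delta E = 0$) the ICER is undefined and the
label falls back to the sign of the incremental NMB.

## Sensitivity analyses

**One-way**: `one_way_sa()` addresses any configuration scalar by a dotted
path (e.g. `arms.bev_pacl.pre_progression_cycle_costs.drug_acquisition`),
reruns the full pipeline at the low and high values and reports ICERs or
dominance labels. Survival variations of ±50% are expressed as
multiplicative variation of the relevant hazard-ratio link (comparators)
or of `survival_spec.<endpoint>.hazard_multiplier` (the reference arm's
own curves): hazards and HRs are the only survival levers the model has,
and scaling them is the conventional reading of such ranges.

**Structural scenarios**: `scenario_run()` switches the extrapolation
family, substitutes an alternative survival input set (e.g. a different
radiological assessment of PFS), applies fixed post-progression survival,
half-cycle correction, RDI, or the from-start discounting convention.
Under fixed post-progression survival the OS curve no longer governs the
post-progression state: every cohort fraction leaving pre-progression is
treated as progressing and dies exactly the fixed number of months later —
a deliberate, simple reconstruction of the death process that preserves
occupancy conservation and absorbing death by construction.

**Probabilistic**: `run_psa()` samples every uncertain parameter
independently per draw — beta for utilities (bounded in $[0,1]$), gamma
for costs (non-negative), lognormal for hazard ratios (positive) — with
parameters obtained by closed-form moment matching from the central value
and a dispersion. The source analysis publishes no standard errors, so the
defaults are conventional placeholders: CV 20% for costs and hazard
ratios, SE 0.05 for utilities, each overridable per parameter. Published
probabilistic summaries (e.g. acceptability percentages) are therefore
**not** reproducible targets of this package; the probabilistic machinery
is validated instead by its degenerate, reproducibility and limit
properties (zero dispersion reproduces the deterministic run draw-for-draw;
a seed fully determines the output; the acceptability curve tends to the
cost-saving fraction at zero willingness to pay and the QALY-gaining
fraction as it grows without bound). Draws are independent across
parameters (no correlation structure is published), and the 1,000-draw
Monte-Carlo parameter simulation is itself the "bootstrap" — there is no
patient-level sample to resample. A draw whose sampled parameters violate
a configuration invariant (e.g. a utility pair crossing) fails validation,
is excluded and counted; more than 1% of failures aborts the run.

## Synthetic data

The patient-level trial data behind the reference arm are not publicly
deposited, so the package generates pseudo individual-patient data with a
known parametric truth (`simulate_ipd()`): inverse-CDF event times,
administrative cutoff censoring, and random censoring from an independent
exponential distribution whose rate is solved numerically so the expected
censored fraction hits the target. The censoring distribution is
deliberately *non-informative*; schemes that condition the censoring time
on the event time (e.g. uniform on $(0, T)$) bias both the
maximum-likelihood and Kaplan–Meier estimators and would corrupt the
parameter-recovery checks. `paired_ipd()` draws progression and death
jointly, taking the componentwise minimum for the PFS endpoint so
progression never follows death.

The packaged base case (`base_case_fixture()`, also shipped as
`inst/extdata/base_case_config.yaml`) carries the published cost inputs
exactly, but its survival parameters (Weibull PFS shape 1.3 / scale 10,
OS shape 1.3 / scale 34, medians ≈ 7.5 and ≈ 26 months) and hazard-ratio
chains (PFS 1.30 / 1.49, OS 0.98 / 0.96) are **synthetic placeholders**:
the source analysis prints neither its fitted survival parameters nor its
numeric indirect-comparison hazard ratios. Consequently the fixture
reproduces the qualitative published pattern (the reference arm is cost
saving against both comparators, and gains QALYs while forgoing life years
against BEV+PACL) but its absolute totals are not, and cannot be, the
published ones. What passing tests show about real data is therefore: the
arithmetic of every stage is correct on inputs with known truth; they do
not show that the placeholder efficacy inputs match any trial.

## Numerical choices and problem sizes

* Occupancy conservation is asserted to $10^{-9}$ at every cycle; death
  occupancy is non-decreasing by construction in both the standard and
  fixed-post-progression-survival traces.
* Accrual is validated against closed-form finite geometric series for
  exponential curves with flat costs (relative tolerance $10^{-6}$).
* Fitting is deterministic given data: `flexsurv`'s data-derived starting
  values, no randomized restarts.
* Parameter recovery of the Weibull fit is checked on generated data at
  n = 200, 1,000 and 5,000 with 20% censoring (shape within ±0.1 and
  scale within ±0.5 at n = 5,000); Kaplan–Meier sup-distance to the truth
  curve is checked at n = 10,000 (≤ 0.02 inside the 95th percentile of
  follow-up).
* Test and validation problem sizes (horizon 180–240 months, PSA 1,000
  draws, 1,000 randomized trace pairs, 10,000 randomized incremental
  pairs) were chosen so the whole suite validates every stated property at
  comfortable statistical resolution.
* Monetary arithmetic is floating point; printed euro amounts round half
  away from zero (`round_half_up()`), matching how the published tables
  present whole-euro figures; delimited outputs carry 2 decimals for euros
  and 3 for QALYs/LYs.

## Known limitations

* The partitioned-survival construction cannot express post-progression
  mortality that depends on time since progression (except through the
  fixed-survival scenario); there are no tunnel states and no
  individual-level simulation.
* No age-dependent background mortality is added to the trial-derived OS.
* Extended dominance and efficiency frontiers across more than two arms
  are out of scope; comparisons are pairwise against the reference arm.
* Prices are opaque configuration constants at their published 2013/2014
  values; no inflation adjustment or bottom-up price re-derivation is
  attempted.
* The indirect-comparison hazard ratios are mandatory inputs with no
  package-supplied defaults beyond the clearly flagged synthetic
  placeholders of the fixture.

## A worked base-case run

```{r}
cfg <- base_case_fixture()
res <- run_model(cfg)
res
```

```{r}
sa <- one_way_sa(cfg, list(
  list(path = "arms.bev_pacl.pre_progression_cycle_costs.drug_acquisition",
       low = 2000, high = 5000)))
sa[, c("parameter", "comparator", "low_result", "high_result")]
```

```{r}
psa <- run_psa(cfg, n_draws = 200, seed = 1)
ceac(psa, c("eve_exe", "bev_pacl"), wtp_grid = c(0, 36000, 100000))
```
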