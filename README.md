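# psmcea

Partitioned-survival cost-effectiveness modelling for oncology treatment
comparisons, built around a concrete decision problem: everolimus plus
exemestane (EVE+EXE) versus bevacizumab plus paclitaxel (BEV+PACL) and
bevacizumab plus capecitabine (BEV+CAPE) as second-line treatment of
HR+/HER2− metastatic breast cancer, from a third-party-payer perspective.
It is written for health economists and HTA analysts who need a tested,
scriptable implementation of this model class rather than a spreadsheet.

## The model

A three-state cohort model (pre-progression, post-progression, death) on
monthly cycles, with occupancy read directly off the survival curves
(partitioned survival):

    pre(t)  = S_PFS(t)
    dead(t) = 1 − S_OS(t)
    post(t) = S_OS(t) − S_PFS(t)

PFS and OS are extrapolated with parametric families (exponential,
Weibull, Gompertz, log-logistic; maximum likelihood under right censoring,
minimum-AIC selection). Comparator curves come from hazard-ratio chains
applied as a proportional-hazards transform `S^HR` (indirect comparison),
with PFS clamped at or below OS. Costs accrue in five components
(treatment & administration, adverse events, pre-progression background,
post-progression background, terminal care); QALYs weight occupancy by
annual utilities (0.7733 pre / 0.4964 post). Arms are compared by
incremental cost `ΔC`, incremental effect `ΔE`, the ICER `ΔC/ΔE` against a
willingness-to-pay threshold (36,000 €/QALY), dominance labels, and net
monetary benefit `λE − C`. One-way, structural and probabilistic
sensitivity analyses (beta/gamma/lognormal sampling, CEAC) rerun the same
pipeline. A synthetic-data module generates pseudo individual-patient
survival data with known truth for fitting and validation.

The packaged base case carries the published per-cycle cost inputs exactly
(e.g. drug acquisition 2,447.75 / 3,806.42 / 3,510.97 €/cycle,
post-progression 1,057.41 €/cycle, end-of-life 823.60 €); its survival
parameters and hazard ratios are clearly flagged synthetic placeholders,
because the source analysis does not print them. See the methods vignette
(`vignettes/psmcea-methods.Rmd`) for the full account.

## A worked example

```r
library(psmcea)

cfg <- base_case_fixture()      # or load_config("inst/extdata/base_case_config.yaml")
res <- run_model(cfg)
res
#> <cea_results> reference arm: eve_exe | WTP 36,000 EUR/QALY
#>   eve_exe    total cost     44,627 EUR | QALYs  1.381 | LYs  2.437
#>   bev_pacl   total cost     56,512 EUR | QALYs  1.362 | LYs  2.473
#>   bev_cape   total cost     52,223 EUR | QALYs  1.388 | LYs  2.510
#>   eve_exe vs bev_pacl (QALY): delta cost -11885, delta effect +0.018 -> dominant
#>   eve_exe vs bev_pacl (LY): delta cost -11885, delta effect -0.036 -> less_effective_and_cheaper
#>   eve_exe vs bev_cape (QALY): delta cost -7596, delta effect -0.007 -> less_effective_and_cheaper
#>   eve_exe vs bev_cape (LY): delta cost -7596, delta effect -0.073 -> less_effective_and_cheaper
```

Reading this: with the packaged (partly synthetic) inputs, EVE+EXE costs
11,885 € less than BEV+PACL over a lifetime and gains 0.018 QALYs, so it
*dominates* that comparator; on the unweighted life-year scale it is
cheaper but loses 0.036 LYs (southwest quadrant, labelled
`less_effective_and_cheaper`) — quality-adjustment flips the sign because
EVE+EXE shifts survival time into the higher-utility pre-progression
state.

Probabilistic uncertainty and the acceptability curve:

```r
psa <- run_psa(cfg, n_draws = 1000, seed = 1)
ceac(psa, c("eve_exe", "bev_pacl"), wtp_grid = 36000)
#>     wtp probability
#> 1 36000       0.893
```

A command-line wrapper over the same functions ships in `inst/cli/cea`
(subcommands `run`, `psa`, `owsa`, `simulate-ipd`).

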