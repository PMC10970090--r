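# zolnet

Shared-patient network analysis of zolpidem prescription claims.

Zolpidem — a controlled non-benzodiazepine hypnotic — is among the drugs most
exposed to *doctor shopping*: patients visiting multiple institutions to
obtain repeated prescriptions. `zolnet` implements a claims-based pipeline for
studying this behaviour in a cohort of chronic users aged 40–80: it classifies
users into low- and high-dose groups by annual consumption, contrasts the
directed institution networks their visits induce, and models the patient-level
risk factors of high-dose use. Because real national-insurance claims are
access-restricted, the package ships a seeded synthetic claims generator whose
statistical structure (demographics, dose-group propensities, group-dependent
shopping intensity) makes every downstream stage testable end to end.

The package is aimed at pharmacoepidemiologists and health-services
researchers who work with outpatient claims (one row per dispensing visit plus
a patient attribute table) and want reproducible, tested building blocks
rather than one-off scripts.

## The analysis

**Dose classification.** With 10 mg tablets and the WHO Defined Daily Dose of
10 mg/day, one tablet is one DDD. A patient's index-year consumption
`T = Σ tablets_dispensed` classifies them as a *low-dose* (`T ≤ 360`) or
*high-dose* (`T > 360`) user.

**Cohort selection.** A flowchart funnel keeps county residents aged 40–80
with ≥ 4 prescription events in the year before the index year and ≥ 1 in it,
excluding presumed-deceased patients, records with missing mandatory fields
and duplicated ids, and reports a per-filter attrition trace.

**Shared-patient networks.** For each dose group, institutions are nodes and a
directed edge `A → B` records patients visiting `A` strictly before `B`
(precedence mode; a consecutive-transition mode is also available). Edge
weights count patients and are displayed as `log10(1 + w)`. Three indicators
summarise each network:

- *density* `= |E| / n(n−1)` — how completely patients' movements connect the
  ordered institution pairs;
- *in-degree* of a node — the number of distinct institutions patients had
  visited before arriving there;
- *betweenness centrality*
  `B(v) = Σ_{s≠t≠v} σ_st(v) / σ_st` over ordered pairs, with `σ_st` the number
  of shortest directed paths — the institution's importance as a bridge.

Psychiatrist-prescribed visits can be collapsed into a single aggregate node
to quantify the specialty's role in the network.

**Risk regression.** High-dose membership is modelled by multivariable
logistic regression on gender, age band, insurance-premium band, catastrophic
illness certification, chronic disease and reason-for-visit indicators,
reported as adjusted odds ratios `aOR = exp(β)` with Wald 95% CIs, optionally
after SPSS-style stepwise selection (entry p < 0.05, stay p ≤ 0.10).

## Worked example

```r
library(zolnet)

cfg    <- generator_config(n_patients = 2000, seed = 42)
claims <- simulate_claims(cfg)

sel  <- select_cohort(claims$patients, claims$visits)
glance(sel)
#>   n_input n_cohort n_removed index_year
#> 1    2000     1649       351       2008

dose <- classify_dose(claims$visits, sel)
round(group_proportions(dose), 4)
#>    low   high
#> 0.7665 0.2335

net_high <- build_network(claims$visits, dose, group = "high")
net_low  <- build_network(claims$visits, dose, group = "low")
glance(net_high)$density   # 0.820
glance(net_low)$density    # 0.584

fit <- fit_logistic(regression_data(sel$patients, dose))
tidy(fit)
#>    term                     aOR conf.low conf.high  p.value
#>  1 gendermale              1.32     1.03      1.70  2.9e-02
#>  2 age_band40-50           2.06     1.44      2.96  8.1e-05
#>  7 catastrophic_certTRUE   2.04     1.56      2.66  1.9e-07
#>  9 reason_mood_disorderTRUE 3.42    2.67      4.38  1.3e-22
#>  ...
```

Of 2,000 simulated patients, 1,649 survive the funnel and 23.4% are high-dose
users. The high-dose network is denser than the low-dose one (0.82 vs 0.58):
high-dose patients spread their visits across more institutions, so their
movements connect far more ordered institution pairs even though the group is
three times smaller. The regression recovers the generating risk factors —
e.g. mood-disorder visits carry an adjusted odds ratio of 3.4 (95% CI
2.7–4.4) for high-dose membership.

`run_pipeline(pipeline_config(...), out_dir)` executes all stages and writes
`patients.csv`, `visits.csv`, `attrition.csv`, `dose_groups.csv`, per-group
GraphML + edge lists, `metrics.json`, `regression_table.csv` and a manifest;
`autoplot()` methods draw the network, the attrition funnel and an aOR forest
plot. A command-line wrapper lives at `inst/cli/zolnet.R`, and
`inst/extdata/demo_config.yaml` is a ready-made demonstration configuration.

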