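---
title: "Modelling medication-seeking networks in prescription claims"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling medication-seeking networks in prescription claims}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zolnet)
```

`zolnet` studies doctor shopping for zolpidem in outpatient claims through
four linked models: a cohort-selection funnel, a Defined-Daily-Dose
classification, directed shared-patient institution networks, and a logistic
risk-factor regression. This vignette explains each model, its assumptions
and tunable parameters, what the synthetic claims generator does and does not
emulate, and the numerical and design choices a maintainer should know about.

## The cohort and the dose threshold

The analysis targets *chronic* users aged 40–80 in one county: patients with
at least four zolpidem prescription events in the year before the index year
and at least one in the index year. A "prescription event" is a visit record
with `tablets_dispensed > 0` — the inclusion rule counts dispensing events,
not tablets. Filters are applied in a fixed order (residence → age →
deceased → prior-year frequency → index-year presence → missing fields →
duplicate ids) with *first-failure attribution*: a patient failing several
filters is counted once, at the first failing filter, so the attrition trace
partitions the input exactly. Permuting the filter order cannot change the
final cohort, only the per-step attribution; `select_cohort()` exposes the
order as an argument and the tests exercise this property.

Two conventions are worth flagging. Age is evaluated as the recorded
`age_years` against an inclusive 40–80 window — a fixed reference rather than
a per-visit age, which keeps the filter deterministic. The "duplicates"
filter collapses repeated `patient_id` rows, keeping the first; in real
registries repeated enrolment records are heterogeneous, and treating them as
duplicate ids is the package's interpretation of that step.

With 10 mg tablets and the WHO DDD of 10 mg/day for zolpidem, one tablet is
one DDD, so the classification works directly on tablet counts: annual
consumption of more than 360 tablets (≈ one tablet a day) marks a high-dose
user; exactly 360 is low-dose. The threshold, tablet strength and mg/DDD are
all arguments of `classify_dose()`, so other strengths need no code change.
A prescription's tablets are attributed entirely to the calendar year of its
visit date; a late-December 90-day refill therefore counts in the dispensing
year. Cohort members without an index-year record are a *contract violation*
(an error naming the patient), since upstream selection guarantees at least
one.

## Directed institution networks

Institutions are nodes; patients' temporally ordered visits induce directed
edges. Because claims give at most a date (not a time), same-day visits are
ordered by the package-wide total order *(visit date, institution id, record
ordinal)* — precedence edges need a total order, and this one is
reproducible from the emitted files alone.

Two edge semantics are implemented because claims analyses use both:

- **precedence** (default): `A → B` when a patient visits `A` strictly
  before *some* visit at `B`. This matches the in-degree reading "how many
  institutions had the patient visited before arriving here", and is the
  semantics under which a hub receiving patients from 20 feeder institutions
  has in-degree 20.
- **consecutive**: edges only between adjacent visits in a patient's
  sequence. Its edge set is always a subset of the precedence edge set
  (tested).

Precedence weights count *patients*, not visit pairs, to stop frequent
revisits from inflating an edge; `weight_by = "pairs"` switches to ordered
visit-pair counting. Display weights are `log10(1 + w)`, the conventional
transform for drawing edge thickness. Out-of-county institutions stay in the
graph flagged `in_county = FALSE` (a `county_only` filter removes them), and
`psychiatrists = "aggregate"` reroutes every psychiatrist-prescribed visit to
a single aggregate node *before* edge construction — the package treats "the
psychiatrists" as one actor rather than one node per hospital department,
which is the simplest reading consistent with reporting a single psychiatrist
in-degree; the aggregation never increases the node count and never changes
the visit count (tested invariants).

Metrics are deliberately unweighted: density is `|E| / n(n−1)` (0 below two
nodes), in-degree counts distinct predecessors, and betweenness sums
`σ_st(v)/σ_st` over ordered pairs on unweighted shortest paths, unnormalised
by default (NodeXL-style raw scores; `normalized = TRUE` divides by
`(n−1)(n−2)`). Unreachable pairs contribute zero. The implementation sits on
igraph; the test suite checks it against an independent exhaustive oracle —
distances from boolean adjacency powers, path counts from
`σ_st = (A^{d_st})[s,t]`, betweenness from the counting identity — on 200
random digraphs of up to 8 nodes, plus closed-form cases (for instance,
every node of a directed 4-cycle scores exactly 3: twelve internal path
slots shared by four nodes).

## The risk model

High-dose membership is modelled as
`logit P(high) = β₀ + x'β` with reference levels female, age 71–80, premium
band > NTD 40,000/month, no certification, no chronic disease, and no flag
for each visit-reason indicator. Reason covariates enter as ever/never
indicators per patient — no temporal disease dynamics. Estimation is
maximum likelihood via iteratively reweighted least squares (`glm`,
tolerance 1e-10, up to 100 iterations); standard errors come from the
observed information, and intervals are Wald, `exp(β ± 1.96·SE)` —
symmetric on the log scale, as in the SPSS-style output this table layout
mirrors. Reference rows carry aOR exactly 1 and no interval. Two failure
modes are errors, not warnings: quasi-complete separation (a coefficient
beyond ±15) names the covariate, and rank deficiency names the collinear
columns.

Stepwise selection follows the SPSS default family: forward entry of the
candidate with the smallest term-level Wald p below `entry_p = 0.05`,
backward removal of any included term above `stay_p = 0.10` after each
entry, lexicographic tie-breaks, termination when nothing moves (with an
oscillation guard). Term-level tests are joint Wald chi-squares, so a
multi-level factor enters or leaves as a block. With `entry_p = stay_p = 1`
the procedure degenerates to the full-model fit, which the tests use as an
identity check. Note one structural property of p-value stepwise: a
pure-noise candidate enters at about the `entry_p` rate by construction, so
"noise excluded" can never hold more often than about 95% of runs at the
default threshold.

## What the generator emulates — and what it does not

The generator is two-stage. Stage one draws independent patient covariates
at fixed marginals: 63.95% female; age bands 24.76 / 28.70 / 23.38 / 23.16%
across 40–50 / 51–60 / 61–70 / 71–80; premium bands 18.88 / 73.16 / 7.96%;
22.80% certification; 97.75% chronic disease; configurable ever-prevalences
for the reason categories. A *latent* dose group is then drawn from the
logistic model above with log-odds equal to the adjusted odds ratios the
regression is meant to recover (male 1.33, age 40–50 1.63, age 51–60 1.23,
age 61–70 1.04, premium low 1.40, premium mid 0.84, certification 2.08,
chronic disease 4.27, mood disorder 3.93, hypertension 1.31, other emotional
disturbances 1.77, gastrointestinal disease 1.64, coronary heart disease
1.80, degenerative arthritis 1.56). The latent group parameterises stage
two and is never emitted: the observable group is recovered from dispensed
tablets.

The intercept is calibrated by root finding so that the *cohort-level*
high-dose fraction is 22.82%. The published marginal describes patients who
survived the inclusion rule, and low-visit-rate (mostly low-dose) patients
fail the four-prescription rule more often; the calibration therefore
weights each latent group by its analytic probability of passing the rule
under the configured visit rates and tablet floors. The weighting is exact
under the generator's own independence assumptions.

Stage two draws, per patient-year, a visit count (Poisson, mean 6 for the
low group and 12 for the high group), an annual tablet target (uniform
integers on [40, 360] for low, [361, 1460] for high — the paper-fixed
360-tablet threshold bounds the low range, and 1460 is a four-tablets-a-day
ceiling), and spreads the target over the visits in near-equal integer
parts, growing the visit count when the 90-tablet per-visit cap (the
90-day refill ceiling) would be exceeded. Within a dispensing year the
tablets sum to the drawn target *exactly* — a conservation law the tests
assert. Each patient owns a personal institution pool of `1 + Poisson(m−1)`
distinct institutions with mean `m` = 2 (low) vs 4 (high): this
doctor-shopping contrast is the single mechanism behind the higher density
of the high-dose network. Visits land uniformly on dates within the year
and on institutions within the pool; 15% of non-psychiatric-hospital visits
are psychiatrist-prescribed; the institution roster (3 regional, 5
district, 40 clinics, 2 psychiatric hospitals; the last 10% per level
out-of-county) is deterministic in the configuration. A small share of
patients is out-of-county (5%), out of the age window (3%) or
presumed-deceased (654/28318 ≈ 2.3%) so that every funnel filter has work
to do. Where no published value fixes a parameter (visit rates, pool sizes,
institution counts, psychiatrist share), the defaults are one-off choices
of plausible county-scale magnitudes, not calibrated values, and are all
exposed in `generator_config()`.

What the generator does **not** emulate: geography (residence is a boolean,
not coordinates), non-zolpidem drugs, inpatient care, temporal disease
dynamics, institution popularity gradients, seasonal prescribing, or
duplicate/missing records (those two filters are exercised by hand-built
fixtures in the tests instead). Consequently, passing tests demonstrate
that the *pipeline* measures what it claims on data with known structure —
they do not validate the behavioural realism of any particular parameter
value, and absolute network metrics at full scale are not comparable to
values computed on real claims, where visits concentrate heavily on a few
institutions. In particular, density saturates with cohort size (more
patients cover more ordered pairs), so per-group density contrasts are
meaningful at a given scale but not across scales.

## Determinism and problem sizes

Every stochastic function takes a seed and derives independent substreams
from it; identical configuration and seed give byte-identical outputs,
including `metrics.json` and the run manifest (config hash + seed + file
list). The test suite and the acceptance script choose problem sizes that
keep the full run in tens of seconds while leaving comfortable statistical
margins: n = 5,290 for descriptive structure, n = 20,000 for
coefficient recovery (each generating log-odds within ±3 SE), 500
simulations at n = 2,000 for Wald CI coverage (93–97% expected), 100
replicates at n = 800 over two years for the density contrast, and 200
random ≤ 8-node digraphs for the metric oracle.

## Known limitations

- The precedence/consecutive choice matters for edge counts; precedence is
  the default because it matches the "visited before arriving" reading of
  in-degree, but both are first-class and exports record the mode.
- Wald intervals undercover for rare cells (e.g. the non-chronic stratum at
  small n); the separation guard turns the worst cases into explicit errors
  rather than silent instability.
- The generator's covariates are mutually independent; real claims
  covariates are correlated, so recovered adjusted and crude odds ratios
  coincide here more closely than they would in practice.
- At demonstration scale a handful of institutions receive most in-degree
  mass by chance alone; rankings (`top_nodes()`) are reported with
  deterministic id tie-breaks for reproducibility, not stability.
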