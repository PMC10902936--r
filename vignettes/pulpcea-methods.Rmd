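---
title: "Modelling the cost-effectiveness of pulpotomy versus root canal treatment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the cost-effectiveness of pulpotomy versus root canal treatment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pulpcea)
```

## The decision problem

A mature permanent tooth with irreversible pulpitis in an 18-year-old can be
treated either by pulpotomy (removal of the coronal pulp, preserving vital
radicular pulp) or by root canal treatment (RCT; complete pulp removal and
obturation). Pulpotomy is far cheaper up front but fails more often, and a
failed pulpotomy typically leads to a salvage RCT or extraction. The package
compares the two strategies over the patient's remaining lifetime from a US
private-payer perspective: costs are ADA 2020 fee-survey charges indexed by
CDT code, effectiveness is measured in tooth-life-years (discounted years of
retention of a healthy treated tooth), and both are discounted at 3% per
year.

## Model structure

`build_dental_model()` encodes each arm as a discrete-time Markov cohort
model with 6-month cycles run by the generic engine in `run_cohort()`:

* The cohort enters the arm's first-year healthy state at cycle 0, when the
  initial intervention plus a direct composite restoration (D2393) and a
  porcelain-fused-to-metal crown (D2751) are charged.
* The first year is a two-cycle tunnel with a per-cycle hazard derived from
  the first-year success probability; later cycles use the follow-up
  complication probability. A reported mean annual failure rate $a$ over a
  period of $y$ years is spread uniformly over its $2y$ half-year cycles
  assuming a constant hazard,
  $$h = 1 - (1 - a\,y)^{1/(2y)},$$
  so that $(1-h)^{2y} = 1 - a\,y$ exactly (`afr_to_cycle_hazard()`).
* A failed treatment occupies a diseased state for exactly one cycle (the
  paper gives no treatment-delay distribution) and then branches: a failed
  pulpotomy receives a salvage RCT (87.5%) or extraction (12.5%); a failed
  RCT receives nonsurgical retreatment (10%), surgical retreatment (15%) or
  extraction (75%). Failure after a retreatment leads to extraction — no
  unbounded retreatment loops.
* Background all-cause mortality applies from every living state as a
  competing risk: the per-cycle death probability is applied first, and the
  declared tooth-level transition probabilities (which sum to one at each
  chance node, using a residual-complement rule for the unlabelled edge) are
  rescaled over the surviving fraction, keeping them interpretable as
  conditional on survival.
* The simulation runs to age 110, by which the life table has closed out.
  There is no half-cycle correction by default: state membership is
  evaluated at cycle start and rewards accrue for the whole cycle at the
  start-of-cycle discount factor. `half_cycle = TRUE` switches to averaging
  start- and end-of-cycle occupancy.

### Which states earn retention credit

Two readings of "tooth-life-years" are supported, and the choice matters:

* `effect_states = "healthy"` (default): the retention reward is attached to
  the arm's healthy states only — time spent symptomatic, under salvage
  treatment, or after retreatment contributes cost but no effectiveness.
* `effect_states = "tooth_in_mouth"`: every state in which the tooth is
  physically present accrues retention.

The default was chosen because it is the reading consistent with the
published base case this analysis re-implements: under it the RCT arm's
discounted retention (16.45 years) matches the published 16.15 within 2%,
whereas crediting all in-mouth states yields 18.4 years for RCT and 21.7 for
pulpotomy — *inverting* the published ordering of the arms, since the
pulpotomy arm's frequent failures are mostly rescued into a durable salvage
RCT. The pulpotomy arm still falls short of the published value under every
reading we examined (12.46 healthy-only versus 15.07 published), which
suggests the original analysis gave partial credit to salvage time or used
period-specific pulpotomy failure rates not printed in its parameter table;
we deliberately did not invent such values.

### Salvage restoration policy

How the salvage RCT after a failed pulpotomy is restored is not stated in
the source parameters. The default, `salvage_restoration = "composite"`,
charges D3330 plus a direct composite restoration: clinically, the RCT is
performed through the existing crown and the access cavity is sealed with
composite. This reproduces the published pulpotomy lifetime cost to within
1%. The alternatives `"none"` (fee only) and `"full"` (new restoration and
crown; under which the pulpotomy arm becomes the *more* expensive strategy
over a lifetime) are available for scenario analysis.

## Background mortality

No vital-statistics life table ships with the package. Instead
`calibrate_gompertz()` generates a Gompertz–Makeham table,
$\mu(x) = \lambda + \alpha e^{\beta x}$, with $\beta = 0.087$ (an adult
mortality-doubling time of about 8 years) and $\lambda = 5\times10^{-4}$
fixed, solving one-dimensionally for $\alpha$ so that the remaining life
expectancy at age 18 equals the 60.6 years the analysis assumes. The
synthetic table reproduces adult mortality shape well but has no infant- or
accident-hump; this is immaterial here because the cohort starts at age 18.
Remaining life expectancy is computed in half-year steps, crediting only
completed half-cycles (a table with $q_x \equiv 1$ gives exactly zero), and
annual probabilities convert to cycle probabilities by
$1-(1-q_x)^{1/2}$. Users with a real life table can supply it as a CSV with
columns `age,qx` (`read_life_table()`).

## Engine numerics

Occupancy rows are checked to sum to one (tolerance $10^{-12}$ in the test
suite); probability errors — explicit values outside $[0,1]$, chance-node
sums away from one, negative residuals — abort with the state and cycle
named. Entry costs are charged to arriving mass at the arrival cycle's
discount factor, with initial occupancy treated as an arrival at cycle 0.
An individual-level microsimulation (`run_microsim()`) resolves the same
transition structure by sampling trajectories and is used in the tests as an
independent Monte Carlo oracle: at $n = 200{,}000$ individuals the cohort
totals agree within three standard errors on both arms.

## Sensitivity analyses

`run_psa()` propagates parameter uncertainty with, per iteration: every
procedure fee drawn from a Gamma distribution with mean equal to the fee and
SD 10% of the mean (shape 100 by moment matching), shared between the two
arms as a common fee schedule; and the first-year and follow-up success
probabilities of both arms drawn from moment-matched Beta distributions with
SD 0.02, with complication probabilities set to the complements so every
chance node still sums to one. Draws are restricted to the 5–95 percentile
band of their own distribution by rejection sampling; this truncation
shrinks the realised SD by roughly 20% (the central-90% factor for a
near-normal distribution is about 0.79), which we document rather than
correct. Parameters are sampled independently; 10,000 iterations and a
fixed seed are the defaults. Both the ICER of means (the headline summary,
since a ratio of means is the standard estimator) and the mean of
per-iteration ICERs are reported, along with central 95% intervals of the
incremental cloud.

Because a ±0.02 shift in a follow-up success probability shifts the
*lifetime* per-cycle failure hazard, the incremental-effect cloud is wide
(SD ≈ 4 tooth-life-years around a mean of ≈ 4). The acceptability curve
therefore rises gently with willingness-to-pay rather than jumping between
0 and 1: at the package defaults the probability that pulpotomy is
cost-effective at 50 USD per tooth-life-year is about 0.54 and the
probability that RCT is cost-effective at 550 USD about 0.81, far from the
published 99.9% anchors. Reproducing near-degenerate acceptability curves
would require effect noise more than an order of magnitude smaller than the
stated Beta SD implies under lifetime-hazard propagation; we report what
the stated uncertainty model produces.

`tornado()` performs one-way analysis: each of the seven fees and the two
follow-up complication probabilities is moved to ±20% of its base value
(probabilities clipped to $[0,1]$; the published figure does not print its
ranges, so they are configurable), the base-case ICER is recomputed at each
end, and parameters are sorted by spread. NMB ties in `ceac()` are awarded
to the cheaper strategy in that iteration — a probability-zero event under
continuous sampling, fixed for determinism.

## Interfaces

All monetary values are floating-point USD, rounded to 2 decimals only at
serialisation. A YAML/JSON configuration file (schema-validated, unknown
keys rejected, omitted keys defaulted; costs keyed by CDT code) drives the
command-line front end:

```sh
Rscript -e 'pulpcea::run_cli()' base --out results
Rscript -e 'pulpcea::run_cli()' psa --iterations 10000 --seed 1 --out results
```

Each run writes CSV artifacts, optional plots, and a JSON manifest
(resolved configuration, seed, package and R versions) sufficient to
reproduce the outputs bit-for-bit on the same platform.

## Problem sizes used in the tests

The packaged test-suite runs the full base case (184 half-year cycles per
arm), the full 10,000-iteration PSA, microsimulation cross-checks at
200,000 individuals, and property checks over randomly generated small
models under fixed seeds.

## Known limitations

* Restorative complications, prosthetic replacement after extraction,
  periodontal complications and canal calcification after failed pulpotomy
  are outside the model, as in the source analysis.
* Follow-up hazards are constant over time; period-specific failure rates
  are not supported.
* Mortality is not sex- or cohort-specific.
* PSA sampling is independent across parameters; no correlation structure
  or value-of-information analysis is provided.
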