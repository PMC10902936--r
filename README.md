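# pulpcea

Decision-analytic cost-effectiveness modelling of **pulpotomy versus root
canal treatment (RCT)** for irreversible pulpitis in mature permanent teeth.

Dentists treating irreversible pulpitis choose between a cheap, conservative
pulpotomy that fails more often and an expensive, highly reliable root canal
treatment. `pulpcea` frames that choice as a discrete-time Markov cohort
model followed over a patient's lifetime from a US private-payer
perspective: an 18-year-old's treated tooth moves through healthy, failed,
salvage-treatment, extracted and dead states in 6-month cycles, accruing
ADA-fee-schedule costs (USD, by CDT code) and **tooth-life-years** of
retention, both discounted at 3% per year. The package is aimed at health
economists and dental-public-health researchers who want a reproducible,
scriptable version of this analysis with its uncertainty machinery.

## What it computes

* **Markov cohort engine** (`run_cohort`) — cycle- and age-dependent
  transitions with a residual-complement rule at each chance node, tunnel
  states for first-year versus follow-up regimes, competing-risk background
  mortality, discounted cost and effect accumulation, plus an
  individual-level microsimulation oracle (`run_microsim`).
* **Hazard conversion** — a mean annual failure rate `a` over `y` years
  becomes a per-6-month-cycle hazard `h = 1 − (1 − a·y)^(1/(2y))`.
* **Synthetic mortality** (`calibrate_gompertz`) — a Gompertz–Makeham life
  table calibrated so remaining life expectancy at 18 equals 60.6 years;
  real tables load from CSV (`age,qx`).
* **Incremental cost-effectiveness** (`icer_ranking`) — ICER = ΔC/ΔE with
  strict and extended dominance; net monetary benefit NMB = λ·E − C;
  acceptability curves (`ceac`).
* **Uncertainty** — one-way tornado analysis (`tornado`) and a 10,000
  iteration probabilistic sensitivity analysis (`run_psa`) with Gamma costs
  (SD 10% of mean), Beta success probabilities (SD 0.02), draws truncated
  to each distribution's 5–95 percentile band.

## Worked example

```r
library(pulpcea)

lt <- calibrate_gompertz(60.6, 18)$life_table  # synthetic US-like mortality
bc <- run_base_case(dental_parameters(), lt)   # Table-1 default inputs
bc$icer
#>     strategy    cost effect incr_cost incr_effect icer       status
#> 1  pulpotomy 2455.36  12.46        NA          NA   NA    reference
#> 2 root_canal 2699.60  16.45    244.24           4 61.1 nondominated
```

Pulpotomy costs 2455 USD over a lifetime and yields 12.46 discounted
tooth-life-years; RCT costs 244 USD more and yields 4.0 more years of
retained healthy tooth, so buying the extra retention costs about 61 USD
per tooth-life-year. Whether that is worthwhile depends on the
willingness-to-pay threshold:

```r
psa <- run_psa(dental_parameters(), lt, psa_spec(iterations = 1000, seed = 1))
ceac(psa$results, c(50, 550))
#>   wtp   strategy probability
#> 1  50  pulpotomy       0.531
#> 2  50 root_canal       0.469
#> 3 550  pulpotomy       0.189
#> 4 550 root_canal       0.811
```

At 50 USD per tooth-life-year pulpotomy is the cost-effective choice in 53%
of parameter draws; at 550 USD RCT wins in 81% of draws. `plot_ceac()`,
`plot_ce_plane()` and `plot_tornado()` draw the standard figures.

A YAML-configured command line covers the same workflow:

```sh
Rscript -e 'pulpcea::run_cli()' base --out results
Rscript -e 'pulpcea::run_cli()' psa --iterations 10000 --seed 1 --out results
Rscript -e 'pulpcea::run_cli()' ceac --seed 1 --out results
Rscript -e 'pulpcea::run_cli()' tornado --out results
```

See `vignettes/pulpcea-methods.Rmd` for the model structure, the
effect-accrual and salvage-restoration conventions, and known limitations.

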