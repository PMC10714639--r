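# pdrcea

Cost-effectiveness modelling of treatment strategies for proliferative
diabetic retinopathy (PDR), for health-economics and ophthalmology
researchers who need a transparent, testable Markov cohort model rather
than a point-and-click decision tree.

PDR threatens vision and is treated either with panretinal
photocoagulation (PRP) — inexpensive and durable, but causing permanent
peripheral visual-field defect (pVFD) — or with repeated intravitreal
anti-VEGF injection — retina-sparing but costly. `pdrcea` compares four
strategies (PRP only, anti-VEGF only, PRP first, anti-VEGF first) for a
cohort entering at age 50 in the PDR state and followed to age 100.

## The model

An annual-cycle Markov cohort model over the clinical states
{NPDR, PDR, DME, SVL, death}, attribute-expanded (therapy line, last
remission-inducing therapy, ever-PRP flag, DME origin, SVL tenure tunnel
states) so all dynamics are Markovian. Per cycle, death is applied first
(baseline life-table probability `q(age)` × RR 1.49 for diabetes, ×11.54
in SVL, capped at 1), then treatment and progression among survivors.
Discounted lifetime cost (payer, healthcare, societal perspectives) and
QALYs accumulate as

```
Cost_p = Σ_t (1+r)^-t · occ_t' c_p(t),   QALY = Σ_t (1+r)^-t · occ_t' u(t)
```

with `r = 0.045`, rewards on the state occupied at cycle start, no
half-cycle correction. Strategies are compared by incremental
cost-effectiveness ratio `ICER = ΔCost/ΔQALY` vs PRP-only, by efficiency
frontier, and by net monetary benefit `NMB = λ·QALY − Cost` at
willingness-to-pay `λ`; probabilistic sensitivity analysis draws all
parameters from beta / gamma / lognormal / triangular distributions and
summarises the probability each strategy attains maximal NMB as
cost-effectiveness acceptability curves (CEACs). A vectorised
microsimulation oracle validates the cohort trace, and synthetic
generators emulate the non-public inputs (claims-like cost episodes for
macro-costing, EQ-5D-like utility surveys, a Gompertz life table).

See `vignettes/pdrcea-methods.Rmd` for the full model description,
parameter table conventions, and design decisions.

## Worked example

```r
library(pdrcea)

params <- default_parameters()     # published base-case parameter table
lt     <- gompertz_life_table()    # baseline mortality stand-in

results <- run_all_strategies(params, lt)
results
#>         strategy cost_payer cost_healthcare cost_societal    qaly
#> 1       prp-only    11134.8         12686.9       51405.3 11.2765
#> 2  antivegf-only    13719.3         15631.3       44545.9 12.3513
#> 3      prp-first    12670.4         14436.5       47808.2 11.8393
#> 4 antivegf-first    12437.9         14171.3       47496.0 11.8240

incremental_vs_comparator(results, "prp-only", "societal")
#>         strategy comparator    cost    qaly delta_cost delta_qaly icer  label
#> 1       prp-only   prp-only 51405.3 11.2765         NA         NA   NA
#> 2  antivegf-only   prp-only 44545.9 12.3513   -6859.43   1.074780   NA  cost-saving
#> 3      prp-first   prp-only 47808.2 11.8393   -3597.08   0.562786   NA  cost-saving
#> 4 antivegf-first   prp-only 47496.0 11.8240   -3909.29   0.547494   NA  cost-saving
```

Each row is one strategy's expected discounted lifetime cost (2020 USD
per patient) and QALYs. From the societal perspective every anti-VEGF
containing strategy costs less and yields more QALYs than PRP-only
("cost-saving" dominance) — anti-VEGF keeps more of the cohort in
remission, avoiding the severe-visual-loss care costs that dominate the
societal total. From the healthcare perspective the anti-VEGF strategies
buy their extra QALYs at a positive ICER
(`incremental_vs_comparator(results, "prp-only", "healthcare")`).

Sensitivity analyses:

```r
tor <- tornado(strategy = "antivegf-only", comparator = "prp-only")
autoplot(tor)                      # one-way ICER swings, largest first

psa <- psa_run(2000, seed = 1)     # joint parameter uncertainty
cv  <- ceac(psa, perspective = "societal")
autoplot(cv)                       # probability each strategy is optimal
threshold_wtp(ceac(psa, perspective = "healthcare"),
              "prp-only", "antivegf-only")   # CEAC hand-over WTP
```

A YAML-driven reporting layer (`base_case_report()`, `dsa_report()`,
`psa_report()`, `synth_report()`) writes deterministic CSV tables, and
`inst/cli/pdrcea` wraps it as a shell command
(`pdrcea base-case --out results/`).

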