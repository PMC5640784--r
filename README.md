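# hepstat3

Dynamic modelling of IL-6–induced JAK1–STAT3 signalling in primary
hepatocytes: a two-compartment mass-action ODE core (receptor module,
STAT3 nucleocytoplasmic shuttling, SOCS3 negative feedback) with delayed
acute-phase-protein (APP) gene modules downstream, plus the tooling that
typically surrounds such a model:

* **Simulation** — declarative reaction networks compiled to fast R code
  with analytic Jacobians; event-driven protocols (IL-6 steps/washes,
  Ruxolitinib boluses, Stattic, actinomycin D); pre-equilibration.
* **Calibration** — Gaussian likelihood with per-gel scale and per-class
  error nuisances profiled analytically; Latin-hypercube multi-start
  optimization; profile-likelihood 95% intervals that scan until the
  threshold crossing and flag practical non-identifiability.
* **Sensitivity** — local relative sensitivity (LPSA) of each gene's
  integrated 24-h mRNA response, with profile-consistent envelopes.
* **Dose scheduling** — closed-form Ruxolitinib decay/top-up math,
  schedule evaluation against the integrated APP response under a
  concentration cap, exhaustive capped-schedule design, mouse-to-human
  dose scaling.
* **Physiology mapping** — 4-parameter-logistic calibration curves from
  phospho-STAT3 signals to equivalent IL-6 concentrations, with censoring
  at the calibration range and interval-midpoint reporting.
* **Synthetic data** — generators for the full calibration suite
  (immunoblot, qPCR time course and dose response, mass-spec
  phospho-degree, imaging nuc/cyt ratios) and for in-vivo serum/liver
  observations (partial hepatectomy, LPS).

States are nM concentrations, time is hours, IL-6 doses are ng/mL, and
inhibitor doses nM. The committed reference parameterization reproduces
the model's anchor behaviour: pSTAT3 peak at 20 min and Socs3 mRNA peak
at 40 min under 40 ng/mL IL-6, 54.4% STAT3 phosphorylation at 18 min,
nuclear/cytoplasmic STAT3 ratio 1 at rest and 3 at 25 min of 500 ng/mL,
and a Ruxolitinib IC50 of 500 nM. See the methods vignette
(`vignettes/hepstat3-methods.Rmd`) for the model, numerics, and
statistical machinery in detail.

## Quick start

```r
library(hepstat3)
ref  <- reference_parameters()
net  <- build_reference_network(ref)
pvec <- reference_param_vector(ref)

# 40 ng/mL IL-6 time course on a 1-minute grid
tr <- simulate_protocol(net, pvec, stimulation_protocol(40, seq(0, 3, 1/60)))
60 * tr$times[which.max(tr$states[, "pSTAT3"])]    # pSTAT3 peak (min)
#> [1] 20
60 * tr$times[which.max(tr$states[, "Socs3RNA"])]  # Socs3 mRNA peak (min)
#> [1] 40
phospho_degree(tr, 18/60)                          # fraction phosphorylated
#> [1] 0.5439933

# Ruxolitinib dosing: the top-up that restores a 500 nM bolus every 8 h
k <- ref$core[["k_rux_deg"]]
compute_topup(500, k, 8)
#> [1] 191.1029
sch <- reference_schedules()
mean(evaluate_schedule(net, pvec, sch$Triple)$integral_normalized)
#> [1] 0.7858913
scale_for_species(sch$Triple, factor = 10)$doses   # human-equivalent doses
#> [1] 50 19 19

# physiology mapping: fit the ex-vivo 4PL curve, invert a liver signal
curve <- generate_exvivo_curve(ref, seed = 1)
fit <- fit_hill4(curve$dose, curve$signal)
print(fit)
#> 4PL fit: y_min 0.0438, y_max 10.08, EC50 7.049 ng/mL, Hill 1.92 (RSS 0.1792)
inv <- invert_signal(fit, signal_mean = 7.0, signal_sem = 0.5)
c(inv$lower, inv$upper, inv$midpoint)              # equivalent IL-6, ng/mL
#> [1]  9.574597 12.233430 10.900000
```

## Analysis workflow

The numbered scripts under `analysis/` form a pipeline that regenerates
every result table under `results/` from scratch (configuration in
`analysis/config.yaml`):

| stage | script | writes |
|---|---|---|
| 1 | `01_generate_data.R` | anchor checks, synthetic calibration suite, in-vivo serum/liver, ex-vivo curve, reference parameters |
| 2 | `02_fit_genes.R` | per-gene module fits (core frozen), multi-start waterfalls |
| 3 | `03_profiles.R` | profile-likelihood 95% intervals and grids (Fgg, Apcs) |
| 4 | `04_sensitivity.R` | LPSA table over all 48 dynamic parameters |
| 5 | `05_dose_schedules.R` | Single-vs-Triple schedule comparison, capped schedule design, species scaling, IC50 |
| 6 | `06_physiology.R` | 4PL fit of the generated ex-vivo curve, liver signal inversion per condition |
| 7 | `07_report.R` | `results/report.md` summarizing the run |

Run them in order from the repository root:

```sh
for s in analysis/0*.R; do Rscript "$s"; done
```

## Tests

```r
testthat::test_dir("tests/testthat", package = "hepstat3",
                   load_package = "installed")
```

`tests/testthat/test-acceptance.R` contains one block per acceptance
criterion (parameter count, dosing math, reference anchors, midpoint
reporting and 4PL round-trip, in-vivo generator means, and the property
suites including a 20-repetition parameter-recovery study).

`scripts/acceptance.R` recomputes the headline target quantities from
scratch and writes them as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out targets.json
```
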