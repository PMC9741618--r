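# emulacomp

Target-trial emulation for competing risks with inverse probability of
treatment weighting.

## What this package is for

Comparative-effectiveness questions like *"does initiating metformin
rather than a sulfonylurea change the long-run risk of dementia?"*
cannot be answered by feasible randomized trials — dementia's
preclinical phase outlasts any trial — and answering them from
electronic health records runs into two structural problems at once:
treatment is confounded by indication (sulfonylurea initiators are
older and sicker), and death is a competing risk that can distort naive
dementia comparisons (a life-prolonging drug leaves more survivors at
risk of dementia). `emulacomp` implements, as a tested and reusable
pipeline, the causal analysis for this setting:

* **cohort construction under an explicit trial protocol** — new-user
  active-comparator design, eligibility criteria (age, history, prior
  exposure, monotherapy, prevalent disease, CKD), a one-year
  run-in/washout, and an auditable attrition (consort) report;
* **emulated randomization** — propensity scores by logistic
  regression with explicit missing-data categories, stabilized ATE
  weights $w_i = \hat P(A{=}a_i)/\hat P(A{=}a_i \mid C_i)$ (ATT weights
  for sensitivity), and standardized-mean-difference balance tables;
* **the competing-risks estimation core** — weighted cause-specific
  Cox partial likelihood (Breslow ties, Newton–Raphson, weighted
  Lin–Wei sandwich variance), weighted Breslow baseline cumulative
  hazards, plug-in counterfactual cumulative incidence curves
  $\widehat{CIF}_a(t,k)$ with companion survival
  $\hat S_a(t)=\exp\{-\hat H_{01}(t)e^{\hat\beta_1 a}-\hat
  H_{02}(t)e^{\hat\beta_2 a}\}$, risk-difference curves
  $\widehat{RD}(t,k)=\widehat{CIF}_1-\widehat{CIF}_0$, weighted
  Kaplan–Meier and Aalen–Johansen comparators, Schoenfeld/log-rank
  proportional-hazards diagnostics, and per-stratum reweighted
  subgroup analyses;
* **Bayesian bootstrap inference** — every subject reweighted by
  $V_i/\bar V$, $V_i\sim\mathrm{Exp}(1)$, the whole chain (propensity
  fit included) re-run per replicate, pointwise percentile bands from
  500 replicates;
* **a synthetic-data module** — competing-risks cohorts with known
  ground truth (and an exact `true_cif` oracle) plus raw EHR-style
  tables with planted protocol violations whose attrition is fixed by
  construction.

## Worked example

```r
library(emulacomp)

params  <- default_sim_params(10000)          # known truth: HR 0.8 dementia, 0.6 death
records <- simulate_cohort(params, seed = 7)
records
#> Event records: 9543 subjects (5687 arm 1 / 3856 arm 0); events: 1591 dementia, 1214 death, 6738 censored
#> Covariates: age_z, sex_male, hypertension

fit <- fit_propensity(records, c("age_z", "sex_male", "hypertension"))
w   <- compute_weights(fit, "ATE", stabilized = TRUE)
w
#> ATE stabilized weights: n = 9543, mean = 1.000, range [0.543, 2.796]

cfg    <- emulation_config(c("age_z", "sex_male", "hypertension"), B = 100, seed = 7)
bundle <- run_emulation(cfg, records = records)
bundle
#> Target-trial emulation report
#>   n = 9543, estimand = ATE, B = 100, seed = 7
#>   HR dementia:  0.782 (95% CI 0.707-0.861)
#>   HR death:     0.609 (95% CI 0.557-0.678)
#>   HR all-cause: 0.702 (95% CI 0.658-0.756)

rd <- bundle$main$rd_dementia
100 * step_eval(rd$time, rd$rd, 5)
#> [1] -2.11
```

Reading the output: the weighted cause-specific hazard ratios recover
the planted truths (0.8 and 0.6) within sampling error, with Bayesian
bootstrap intervals covering them; the negative 5-year risk difference
(−2.11%) says that universal metformin initiation would lower the
absolute 5-year dementia risk in this synthetic cohort by about two
percentage points relative to universal sulfonylurea initiation,
accounting for death as a competing risk. `bundle` also carries balance
tables before/after weighting, Kaplan–Meier and Aalen–Johansen curves,
PH diagnostics, and (when configured) ATT, covariate-adjusted and
subgroup sensitivity results; `run_emulation(..., out_dir = )` writes
them as CSV/JSON.

Raw EHR-style tables flow through the same pipeline:

```r
tabs  <- simulate_ehr_tables(default_sim_params(500),
                             c(under_age = 3, baseline_dementia = 2), seed = 1)
built <- apply_eligibility(tabs, protocol_spec())
built$attrition                      # per-criterion exclusions, counts conserved
```

A thin command-line wrapper (`inst/scripts/emulacomp`) exposes
`simulate`, `cohort` and `run` subcommands over the same functions.

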