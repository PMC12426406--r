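# busulpk

Semi-mechanistic population pharmacokinetics of intravenous busulfan in
children undergoing haematopoietic cell transplantation — for
pharmacometricians and clinical-pharmacology researchers who need the
full pipeline from structural model to dose recommendation in one tested
R package.

Busulfan conditioning has a narrow window: cumulative exposure (cAUC)
over the 16-dose course should land in 78–101 mg·h/L, while peak
concentrations above ~1.88 mg/L raise the risk of sinusoidal obstructive
syndrome. Clearance in children varies with body composition and
maturation, and — because busulfan is eliminated by glutathione (GSH)
conjugation — the drug depletes the cofactor pool it depends on, making
elimination state-dependent.

## The model

A two-compartment infusion model whose elimination is modulated by a
normalised, resynthesised GSH pool:

    dA1/dt    = R(t) − (CL·A_GSH/Vc)·A1 − (Q/Vc)·A1 + (Q/Vp)·A2
    dA2/dt    = (Q/Vc)·A1 − (Q/Vp)·A2
    dA_GSH/dt = k_GSH·(1 − A_GSH) − (S_GSH/Vc)·A_GSH·k10·A1,   k10 = CL/Vc

with covariates: allometric normal-fat-mass scaling (exponents 0.75 on
clearances, 1 on volumes), a sigmoid postmenstrual-age maturation
fraction on CL (TM50 = 45 wk, Hill = 1.11), and measured
glutathione-S-transferase activity scaling the depletion factor
exponentially. Random effects: log-normal between-subject variability on
CL/Vc/Vp, inter-occasion variability on CL, combined
proportional + additive residual error.

On top of the model sit:

* `fit()` — FOCE with η–ε interaction (compiled ODE core, warm-started
  inner modes, SEs from the numerical Hessian, condition number,
  shrinkage), `covariate_step()` stepwise selection (ΔOFV 3.84 / 10.83)
* `pcvpc()`, `bootstrap()`, `prediction_metrics()`, `cwres()`,
  `gof_tables()` — model qualification
* `run_virtual_trial()`, `optimize_dose()` — Monte-Carlo probability of
  target attainment under weight-band / age-band / fixed mg/kg dosing
  and grid-based dose recommendation
* `generate_population()`, `generate_study_dataset()` — synthetic
  cohorts and full study datasets matching the paediatric study design
  (12 doses q6h, rich day-1 sampling, troughs, terminal profiles)

## Worked example

Exposure and target attainment for the typical 1.4-year-old, 9.9 kg
patient under the weight-band (1.2 mg/kg) and age-band (1 mg/kg)
strategies:

```r
library(busulpk)
pop  <- population_parameters()      # final-model estimates
tp   <- subject_covariates("typical", postnatal_age = 1.4, wt = 9.9,
                           gestational_age = 38.3, ffm = 8.8, gst = 10.12)
individual_parameters(pop, tp)
#> <individual_parameters> CL 1.63 L/h  Vc 4.1 L  Q 1.89 L/h  Vp 2.34 L  S_GSH 0.00266 h/mg

spec <- trial_spec(n_rep = 2000, seed = 1)
run_virtual_trial(list(tp), dose_strategy("wt_band"), pop, spec)
#>        id dose_mgkg dose_mg pta_cauc cauc_median cauc_p5 cauc_p95 ... pta_cmax cmax_median
#> 1 typical       1.2   11.88     21.8    118.1925 77.8238 176.4886 ...    92.95     1.58891
run_virtual_trial(list(tp), dose_strategy("age_band"), pop, spec)
#>        id dose_mgkg dose_mg pta_cauc cauc_median  cauc_p5 cauc_p95 ... pta_cmax cmax_median
#> 1 typical         1     9.9       36     98.2871 64.75267 146.8347 ...     99.9    1.324019
```

Read: at 1.2 mg/kg the typical patient's median cumulative exposure
(118 mg·h/L) overshoots the 78–101 mg·h/L window (22% of replicates land
inside it) and ~7% of replicates breach the first-dose peak limit; at
1 mg/kg the median sits at 98 mg·h/L with 36% attainment and essentially
no peak-limit violations — the same qualitative pattern that makes
weight-band dosing of 9–16 kg children the risk group for sinusoidal
obstructive syndrome.

A full synthetic study and refit:

```r
cohort <- generate_population(demographics_spec(n_subjects = 55), seed = 11)
ds     <- generate_study_dataset(cohort, pop, study_design(), seed = 11)
fit(ds, model_spec(), population_parameters(theta_cl = 12))
```

A thin command-line layer (`inst/cli/busulpk`, YAML configs) drives the
same functions: `generate`, `simulate`, `fit`, `evaluate`, `trial`,
`optimize`.

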