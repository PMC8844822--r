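# nadkin

Steady-state kinetic analysis for multifunctional NAD(P) glycohydrolases —
enzymes such as SARM1, CD38 and *Aplysia* ADP-ribosyl cyclase that consume
NAD(P) through an ordered Uni-Bi mechanism: the pyridine base (nicotinamide)
leaves first, and the ADP-ribosyl intermediate is then resolved by water
(hydrolysis, → ADPR), by intramolecular attack (cyclization, → cADPR), or by
a free pyridine base (base exchange / transglycosidation, → a dinucleotide
analog such as NaAD or AcPyrAD).

`nadkin` is aimed at enzymologists who measure multi-analyte HPLC time
courses and initial-rate tables for these enzymes and need a reproducible
path from raw concentrations to kinetic constants. It provides:

- **Rate laws.** Closed-form evaluation of five laws, with fixed units
  (concentrations µM, rates mU/mg where 1 U = 1 µmol/min):

  | model | law |
  |---|---|
  | eq1 | v = V<sub>max</sub>S / (K<sub>m</sub> + S) |
  | eq2 | v = V<sub>max</sub>S / (K<sub>m</sub> + S(1 + S/K<sub>is</sub>)) — substrate inhibition at the catalytic (TIR) site |
  | eq3 | v = V<sub>max</sub>S / ((K<sub>m</sub> + S(1 + S/K<sub>is</sub>))(1 + S/K<sub>ia</sub>)) — plus the allosteric (ARM) site |
  | eq4 | activity fraction = 1 / (1 + I/IC<sub>50</sub>) |
  | eq5 | v = V<sub>max</sub>S / (K<sub>m</sub>(1 + (I/K<sub>i</sub>)ⁿ) + S(1 + (I/(aK<sub>i</sub>))ⁿ)) — multi-site mixed inhibition |

  plus curve maxima (S_opt = √(K<sub>m</sub>K<sub>is</sub>) and the numeric
  dual-site optimum), k<sub>cat</sub> from crude specific activity, and
  catalytic efficiency k<sub>cat</sub>/K<sub>m</sub>.
- **Product accounting.** Initial-rate window selection (≤ 20% substrate
  consumed, linear product accumulation), OLS rate estimation,
  hydrolysis/cyclization/base-exchange partitions, mass-balance checks,
  profile normalization, immunoblot standard curves and
  internal-standard-corrected metabolite levels.
- **Fitting.** Box-constrained Levenberg–Marquardt with deterministic
  multistart, censoring of unidentifiable inhibition constants ("> 8000 µM"),
  AICc model selection, Lineweaver–Burk diagnostics with secondary replots,
  IC50 and mixed-inhibition fits with competitive/noncompetitive/mixed
  classification, and effector-titration competition analysis.
- **Synthetic data.** Noisy initial-rate grids from any law and
  mass-conserving branching Uni-Bi progress curves, for parameter-recovery
  studies and fully offline testing.

Everything takes and returns tibbles, supports `tidy()`/`glance()` and
`autoplot()`, and is deterministic given a seed.

## Worked example

Simulate a full-length SARM1/NAD experiment (dual-site substrate inhibition,
K<sub>m</sub> 30.3 µM, V<sub>max</sub> 22.4 mU/mg, K<sub>ia</sub> 324 µM,
catalytic site unbounded) and refit it:

```r
library(nadkin)

truth <- dual_inhibition_params(Km = 30.3, Vmax = 22.4, Kia = 324)
d <- generate_initial_rates(sim_config(truth, cv = 0.05, replicates = 4, seed = 42))
fit <- fit_rate_model(d, "eq3")
fit
#> <kin_fit> model eq3 on 48 points; RSS = 14.689 AICc = -45.408
#>   Km    24.38 ± 3.04
#>   Vmax  20.498 ± 1.26
#>   Kis   > 8000
#>   Kia   368.47 ± 56.4
```

The fit recovers the generating constants within noise, and correctly
reports the catalytic-site constant as censored (the data place no upper
bound on it — the substrate inhibition is attributed to the allosteric
site). The curve optimum and the derived turnover follow:

```r
curve_maximum(fit$params)
#>   S_opt V_opt
#> 1  94.8  13.0
kcat <- kcat_from_specific_activity(fit$params$Vmax, molar_mass = 80.4)
catalytic_efficiency(kcat, fit$params$Km)
#> kcat = 0.0275 s^-1, kcat/Km = 1130 M^-1 s^-1
```

So this preparation turns over ~0.03 NAD per enzyme per second with an
efficiency of ~10³ M⁻¹s⁻¹, and its activity peaks near 95 µM NAD before
allosteric substrate inhibition takes over.

Accounting a progress curve takes one call:

```r
tc <- simulate_time_course(truth, S0 = 250,
                           fractions = c(hydrolysis = 0.9, cyclization = 0.1),
                           protein_conc_ug_ml = 100, duration_min = 30)
acc <- account_time_course(tc)
acc$partition[, c("frac_hydrolysis", "frac_cyclization", "specific_activity_mU_mg")]
#>   frac_hydrolysis frac_cyclization specific_activity_mU_mg
#> 1             0.9              0.1                    11.5
```

i.e. 90% of consumed NAD goes to ADPR, 10% to cADPR, at a specific activity
of 11.5 mU per mg protein over the initial-rate window.

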