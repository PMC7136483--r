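# tamipd

Joint tamoxifen–endoxifen population-pharmacokinetic simulation and
model-informed precision dosing (MIPD) for breast-cancer endocrine
therapy.

## The problem

Tamoxifen is a prodrug: clinical effect tracks its active metabolite
**endoxifen**, formed by CYP2D6, and patients below the proposed endoxifen
steady-state trough target of **5.97 ng/mL** are at risk of treatment
failure. Under one-dose-fits-all 20 mg/day dosing, endoxifen exposure
varies enormously between patients — driven by CYP2D6 genotype (activity
score, AS), age, and CYP-interacting comedication (rifampicin, strong
CYP2D6-inhibiting SSRIs) — and roughly 1 in 5 patients stays below target.

`tamipd` implements, as tested and seeded R code, the full simulation
stack needed to study this problem and compare dosing strategies:

* **Structural model** — one-compartment tamoxifen with lagged first-order
  absorption linked to a one-compartment endoxifen metabolite:

  ```
  dGut/dt   = -ka·Gut                         (dose enters at t + tlag)
  dTam/dt   =  ka·Gut − (CL20/F + CL23/F)/V_TAM · Tam
  dEndx/dt  =  CL23/F · Tam/V_TAM − CL30/F/V_ENDX · Endx
  ```

  solved in closed form (superposed bi-/tri-exponentials), with typical
  parameters CL20/F = 5.77 L/h, CL23/F = 0.493 L/h, V_TAM/F = 1120 L,
  ka = 1.78 h⁻¹, tlag = 0.389 h, and literature-fixed CL30/F = 5.1 L/h,
  V_ENDX/F = 400 L.
* **Covariate model** — proportional (fractional-change) effects of CYP2D6
  AS, SSRIs and rifampicin on the clearances, and a power model of age on
  CL20/F centred at 65 years. The metabolic fraction
  `FM = CL23 / (CL20 + CL23) · 100%` is 7.87 % for the reference patient.
* **Variability hierarchy** — log-normal interstudy, interindividual and
  interoccasion effects on both clearances plus correlated log-scale
  residuals (Ω², Π², Φ², Σ as data in a JSON config).
* **MAP-Bayesian forecasting** — per-patient estimation of the two
  clearance deviations from sparse TDM samples by minimising
  `OFV = Σ(ln C_obs − ln Ĉ)²/σ² + Σ η²/ω²`, then selection of the lowest
  dose from 5–120 mg whose predicted steady-state trough reaches target.
* **In silico trial** — standard (20 mg), CYP2D6-guided (20/40/60 mg by
  phenotype) and MIPD strategies on a 10,000-patient virtual population.
* **Synthetic clinical database** — a six-study generator with the full
  four-level hierarchy, plus variance decomposition with and without
  covariate attribution (`variance_explained()`).

## Worked example

```r
library(tamipd)

# a CYP2D6 intermediate metabolizer (AS 0.5), 55 years old
pat  <- patient_covariates(activity_score = 0.5, age = 55)
ip   <- apply_covariates(cov = pat)
metabolic_fraction(ip)        # 3.48 % (vs 7.87 % reference: AS + age)
css_min(ip, 20)$endoxifen     # 5.68 ng/mL at 20 mg/day -- just below target

# three trough TDM samples after a 40 mg guided run-in
obs <- tdm_observations(time = c(14, 21, 28) * 24,
                        conc = c(4.1, 4.6, 5.0), dose = 40)
fit <- map_fit(pat, obs, inflate_for_trial(random_effects_spec()))
fit$eta
#       cl20       cl23
#  0.3075134 -0.5380683     (endoxifen formation well below typical)
select_dose(fit)
# $dose 60   $capped FALSE   $predicted_trough 7.45 ng/mL

# the three-strategy virtual trial (n = 2,000 here; 10,000 in the
# full-scale runs of scripts/acceptance.R)
pop  <- sample_population(population_spec(
          n = 2000, phenotype_counts = c(gNM = 1730, gIM = 154, gPM = 116)))
spec <- inflate_for_trial(random_effects_spec())
run_trial(pop, spec, strategy_config("mipd"), seed = 1)
# In silico trial -- mipd dosing (seed 1 )
#   group      n  dose(med)   median           IQR     CV%   risk%
#   gNM     1730         20     8.62   7.17-10.2      24.7    5.49
#   gIM      154         40     8.45   7.32-10.3      23.8    5.84
#   gPM      116         40     7.72   6.77-9.01      25.7    6.03
#   All     2000         20     8.52   7.15-10.2      24.7    5.55
```

Interpretation: under MIPD the median trough sits ~40 % above target with
a narrow spread (CV ≈ 25 % vs ≈ 68 % under standard dosing) and only ~6 %
of patients remain below 5.97 ng/mL, versus ~22 % under standard dosing.

A command-line interface wraps the same operations
(`inst/cli/tamipd generate-population | simulate-trial | map-fit |
generate-database`); see `?tamipd_cli`.

## Documentation

The methods vignette (`vignettes/tamoxifen-mipd.Rmd`) describes the model,
its assumptions, all tunable parameters, the synthetic-data generator and
the package's design decisions in detail.
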