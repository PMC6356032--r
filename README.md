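# owbscreen

Screening-level (tier-1) exposure and risk assessment for **co-formulants
in plant protection products** (PPP) under REACH, for the people who handle
them: operators mixing, loading and spraying, workers re-entering treated
crops, bystanders near a treated field, and consumers using amateur
products.

Co-formulant manufacturers rarely know the formulation-level detail
(dilution, crop, per-product rates) that the higher-tier PPP operator
models require. `owbscreen` instead runs a fixed set of worst-case generic
exposure scenarios from a handful of substance inputs — physical state,
vapour pressure, and four DNELs (derived no-effect levels; worker and
general-population, dermal and inhalation) — plus one operational input,
the substance application rate in kg/ha.

## The model

Every direct-handling task uses the unit-exposure kernel of the field's
operator models (BBA for spraying, PHED surrogates for granules/seeds):

    Q        = AR × A                     amount handled, kg/day
    E_dermal = UE_d × Q / bw              mg/kg bw/day
    E_inhal  = UE_i × Q / V_breath        mg/m³
    RCR      = E_dermal / DNEL_dermal + E_inhal / DNEL_inhal

with AR the application rate (kg/ha), A the technique's daily work rate
(20 / 8 / 1 ha/day for boom, air-assisted and hand-held equipment), UE the
unit exposure in mg per kg of substance handled, bw = 70 kg (workers) and
V_breath = 10 m³ per work day. Unit exposures are calibrated by inverting
this kernel on published screening-table anchor rows (UE = E × reference /
Q). On top of the kernel sit:

- a constant-rate-release greenhouse vapour term (well-mixed single zone
  with ventilation) added to indoor hand-held spraying for vapour
  pressures above 0.1 Pa;
- a worker re-entry model (dislodgeable foliar residue × transfer
  coefficient), zero for volatile substances;
- a bystander drift model, always assessed against the general-population
  DNELs;
- seed-treatment loading, treated-seed bagging (concentration-banded
  full-shift surrogates, LEV-reducible) and granule/seed dispersal;
- consumer adaptations: no PPE credit, 60 kg body weight, 0.02 ha/day
  area cap, 75th-percentile unit exposures.

Mixing/loading and application are correlated tasks (same workers), so
combined exposure is formed per technique and the binding technique is the
one with the highest *combined* RCR. Because every exposure is linear in
the application rate, the maximum use rate for a target RCR is solved in
closed form, `rate = target / max(constraint slopes)`, cross-checked by
bisection.

## Worked example

Maximize the use rate of a non-volatile solid co-formulant (vapour
pressure 0.001 Pa; worker DNELs 3 mg/kg bw/day dermal and 11 mg/m³
inhalation; general-population DNELs 1.5 and 2.6) against a target RCR of
0.9, with no protective equipment:

```r
library(owbscreen)

reg   <- default_registry()
subst <- substance("reference co-formulant", "solid", 0.001,
                   dnel_worker_dermal = 3, dnel_worker_inhalation = 11,
                   dnel_general_dermal = 1.5, dnel_general_inhalation = 2.6)
res <- run_full_assessment(
  assessment_request(subst, mode = "maximize", target_rcr = 0.9, reg = reg)
)
res
#> <owb_assessment> reference co-formulant
#>   mode: maximize
#>   rates: tractor 1.156 kg/ha, hand-held 0.7682 kg/ha
#>   combined tractor   worst technique boom     total RCR 0.900
#>   combined hand_held worst technique handheld total RCR 0.900
```

The tractor-mounted group supports 1.16 kg/ha and the hand-held group
0.768 kg/ha before the binding combined task reaches the target RCR of
0.9. The binding task for tractors is the *boom* combination (loading the
wettable powder, RCR 0.675, plus boom spraying, 0.225) even though
air-assisted spraying has the worse single application RCR (0.508) —
summing worst cases across techniques would over-predict. The worst-case
loading permutations and the daily amounts behind the rates:

```r
worst_case(res$ges1$ml)[, c("equipment", "formulation", "dermal",
                            "inhalation", "rcr_total")]
#>                               equipment formulation   dermal  inhalation rcr_total
#> 2      Mixing and loading, boom sprayer          WP 1.981446 0.161754796 0.6751871
#> 7 Mixing and loading, hand-held sprayer      liquid 2.249576 0.003800973 0.7502041

res$daily_amounts
#>   technique      rate daily_amount
#> 1      boom 1.1556770   23.1135407
#> 2  airblast 1.1556770    9.2454163
#> 3  handheld 0.7681966    0.7681966
```

Dermal exposures are mg/kg bw/day, inhalation mg/m³, daily amounts kg/day.
`write_results(res, "out/")` emits the permutation tables as CSV, a
full-precision JSON bundle, and a CSR-style text report. A command-line
front end over the same functions lives at `inst/cli/owb.R`
(`assess`, `maximize` and `fixtures` subcommands); an example run
configuration ships in `inst/extdata/example_run.yaml`.

## Scope notes

PHED, bagging, consumer-spreading and greenhouse default constants are
clearly-tagged synthetic placeholders in the registry (the corresponding
scenarios are exercised by structural tests, not absolute-value
reproduction) and can be replaced through a YAML registry override; see
`inst/extdata/registry_override_example.yaml` and the methods vignette
(`vignettes/owb-methods.Rmd`) for the full model account, parameter
provenance and limitations.
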