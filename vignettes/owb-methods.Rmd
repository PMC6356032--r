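---
title: "Screening-level exposure and risk for co-formulants: models and assumptions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening-level exposure and risk for co-formulants: models and assumptions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(owbscreen)
```

## The problem

Co-formulants — every ingredient of a plant protection product (PPP) other
than the active substance — must be registered under REACH, and for
hazardous substances the registration needs a quantitative exposure
assessment covering the PPP uses. The higher-tier operator-exposure models
used in PPP authorisation require inputs (formulation type, dilution,
crop, per-use rates) that a co-formulant manufacturer typically does not
have. `owbscreen` implements the screening (tier-1) alternative: a fixed
set of worst-case generic exposure scenarios (GES) driven by a single
operational input, the substance application rate in kg/ha, producing
dermal and inhalation exposure estimates and risk characterization ratios
(RCRs, exposure divided by DNEL; RCR below 1 indicates adequate control).

Four scenario families are covered: professional spray application (GES1:
mixing/loading, spraying including greenhouses, plus the indirect worker
re-entry and bystander pathways), professional seed and granular
application (GES2: seed-treatment loading, treated-seed bagging, granule
and seed dispersal), and the consumer analogues of both (GES3/GES4).

## The unit-exposure kernel

Every direct-handling model shares one algebraic kernel. A task is
characterised by a *unit exposure* UE — mg of substance reaching the route
per kg of substance handled — taken from field-study databases (the German
BBA operator model for spraying; PHED surrogate values for granules and
seeds). The daily amount handled is

$$Q = \mathrm{AR} \times A$$

with AR the application rate (kg/ha) and $A$ the technique's daily work
rate (ha/day). Exposure follows as

$$E_\text{dermal} = \frac{\mathrm{UE}_d \, Q}{bw}
\qquad
E_\text{inhal} = \frac{\mathrm{UE}_i \, Q}{V_\text{breath}}$$

with $bw$ = 70 kg for workers (60 kg for consumers and bystanders) and
$V_\text{breath}$ = 10 m³ of air inhaled per work day — the unique
breathing volume that makes the published inhalation rows consistent with
the dermal rows, kept configurable in the registry. Because every term is
proportional to AR, all direct exposures (and the indirect ones below) are
homogeneous of degree 1 in the application rate; this is what makes rate
maximization exact.

### Calibration of the unit exposures

The package does not transcribe the BBA tables directly. Instead, the
registry back-derives the unit exposures from the published screening-table
anchor rows by inverting the kernel, $\mathrm{UE} = E \times
\text{reference} / Q$, at the daily amounts behind those rows: 23.12 kg/day
for the boom sprayer (20 ha/day at the effective rate 1.156 kg/ha), 9.25
kg/day for the broadcast air-assisted sprayer (8 ha/day), and 0.768 kg/day
for hand-held equipment (1 ha/day at 0.768 kg/ha). The printed rates
"1.16" and "0.77" are display roundings: only 23.12/20 = 1.156 and 0.768
make all rows mutually consistent, so those values are treated as exact.
The calibration is validated two ways: every anchor row round-trips
through the forward model to its printed precision, and the tractor
loading unit exposures calibrated from the boom rows independently
reproduce the air-assisted rows at 9.25 kg/day.

Mixing/loading unit exposures depend on the formulation handled (liquid,
wettable powder WP, water-dispersible granule WG); application unit
exposures do not, because dilution in water happens before spraying.

## Greenhouse vapour: the constant-rate-release model

Outdoor spray data reflect aerosol exposure only. For hand-held high-target
spraying indoors (greenhouses) a vapour term is added for volatile
substances (vapour pressure above the 0.1 Pa registry threshold): the
applied amount is released at a constant rate over duration $t_r$ into the
well-mixed air column of height $h$ above one hectare, with first-order
removal by ventilation at $q$ air changes per hour. The T-hour
time-weighted average concentration is

$$\mathrm{TWA} = \frac{1}{T}\left(
  \frac{\mathrm{AR}\,t}{q\,h\,t_r}
  + \frac{\mathrm{AR}\,e^{-qt}}{q^{2}\,h\,t_r}
  - \frac{\mathrm{AR}}{q^{2}\,h\,t_r}
\right)\times 100$$

where the factor 100 converts kg·ha⁻¹·m⁻¹ to mg/m³. The implementation
groups the last two terms through `expm1`, which is algebraically
identical but numerically stable as $q \to 0$, where the expression
approaches the closed no-ventilation limit $100\,\mathrm{AR}\,t /
(2\,h\,t_r)$ (times $t/T$). The worker exposure time $t$ must not exceed
$t_r$ — the model describes the release phase only — and the TWA is
averaged over $T = t$ by default. Registry defaults ($q$ = 1 h⁻¹, $h$ =
4 m, $t_r = t = T$ = 8 h) describe a low-ventilation worst case; they are
placeholders in the sense that no published worked example constrains
them (the reference greenhouse row is non-volatile), and they are fully
overridable.

The test suite checks this term against an independent numeric integration
of the underlying air balance $dC/dt = S - qC$ (via `deSolve`), to a
relative error below $10^{-6}$ over a randomized parameter sweep.

## Indirect pathways

**Worker re-entry.** Dermal exposure from contact with treated foliage:

$$E = \frac{\mathrm{DFR}_0 \times n_\text{app} \times \mathrm{AR}
  \times \mathrm{TC} \times t}{bw \times 1000}$$

with DFR₀ the dislodgeable foliar residue per unit rate (µg/cm² per kg/ha
per application), $n_\text{app}$ = 2 applications, TC the leaf-to-worker
transfer coefficient (cm²/h) and $t$ the task duration. For volatile
substances (vapour pressure **at or above** 0.1 Pa — this model's cut-off
is inclusive, unlike the strict inequality used by the greenhouse and
bystander vapour terms; the two comparisons are implemented as the models
state them, not harmonized) the residue is assumed to have evaporated and
the exposure is zero.

**Bystanders.** Dermal exposure is the areal deposit of the application
rate (1 kg/ha ≡ 0.01 mg/cm², a dimensional identity) times a drift
fraction and the exposed body area, per body weight; inhalation scales a
drift unit exposure by the breathed volume, with a vapour add-on above
0.1 Pa. Bystanders are members of the general population, so their RCR is
always computed against the general-population DNELs even though the row
sits inside a professional scenario — if this constraint binds, it
restricts the professional use rate.

The structural constants of both models (TC = 2500 cm²/h over an 8-h
re-entry task; 18 000 cm² exposed body surface, 60 kg, 1.25 m³/h for 1 h
for the bystander) are fixed at plausible field values, and the remaining
free constants (DFR₀; drift fraction and the bystander inhalation unit
exposure) are back-solved so the published indirect rows (0.8778 mg/kg
bw/day; 0.1512 mg/kg bw/day and 0.0102 mg/m³) reproduce at the tractor
effective rate of 1.156 kg/ha. Which group rate sits behind those
published rows is not stated; 1.156 kg/ha is the choice that reproduces
them, and assessments always evaluate both models at each group's own
rate.

## Seed and granular application

Seed-treatment loading reuses the boom-sprayer loading unit exposures (the
tractor-tank transfer is the analogous task); its daily amount handled is
a registry constant (10 kg/day by default — the on-farm throughput is not
published, so this is a documented placeholder). Treated-seed bagging uses
a full-shift transfer surrogate lookup in the style of ECETOC TRA: base
dermal/inhalation values by physical state and band (dustiness for solids,
vapour-pressure band for liquids), multiplied by a concentration-band
factor, with local exhaust ventilation reducing inhalation by 90 %. It is
the one task independent of application rate. Granule and treated-seed
dispersal uses PHED surrogate unit exposures through the same kernel;
loading of hand-held spreading equipment cannot be estimated separately
and is implicit in the dispersal values. Working clothes are inherent in
the surrogate data, so no additional coverall credit is taken by default.
Granules and treated seeds are taken as non-volatile: no indoor vapour
term.

The PHED, bagging and consumer-spreading constants were not available for
transcription; the registry ships clearly-tagged synthetic placeholder
values of plausible magnitude. Consequently GES2 and GES4 absolute
exposures are exercised by structural tests (linearity, banding
monotonicity, protection monotonicity, golden fixtures derived from the
registry itself), not by published-value reproduction — passing tests
demonstrate the algebra, not the surrogate data.

## Consumer adaptations

Consumers get no protection credit (requesting any PPE is an error, not a
no-op), weigh 60 kg, and treat at most 200 m²/day (0.02 ha; smaller
user-supplied areas are honoured). Spray scenarios use a distinct
75th-percentile unit-exposure series rather than a scalar multiplier on
the geometric means — untrained users sit higher in the exposure
distribution, and the p75/GM ratio is not constant across tasks. The
shipped p75 values are synthetic placeholders constrained to dominate the
geometric means entry-by-entry (a validated registry invariant).

## Worst cases, correlation, and rate maximization

Within each contributing scenario every determinant permutation is
computed and the worst case (highest total RCR) flagged — separately for
the tractor-mounted and hand-held groups, which are reported apart to
allow later refinement. Ties break deterministically on the canonical
enumeration order: technique (boom, air-blast, hand-held), formulation
(liquid, WP, WG), environment (outdoor, indoor), first maximum wins. For
a non-volatile substance the hand-held outdoor and greenhouse application
rows are numerically identical, so the tie-break selects the outdoor
label; the combined RCR is unaffected.

Mixing/loading and application are correlated — the same workers do both
in sequence — so combined exposure is formed *per technique*: the worst
formulation loading estimate plus that technique's worst application
variant, never the cross-technique sum of per-scenario maxima (which
would over-predict). In the reference run this matters: air-blast has the
worst single application RCR (0.508) and boom the worst loading RCR
(0.675), but the boom *combination* (0.900) exceeds the air-blast
combination (0.778) and is the binding task.

In maximize mode the package solves for the largest application rate whose
worst constraint stays at the target RCR. Constraints per technique group:
each technique's combined correlated tasks (worker DNELs), re-entry
(worker dermal DNEL) and bystander (general DNELs). Every constraint RCR
is linear through the origin in the rate, so

$$\mathrm{rate}^\ast = \frac{\mathrm{RCR}_\text{target}}
  {\max_c \text{slope}_c}$$

is exact; a bisection solver on the full forward model cross-checks the
closed form to a relative 10⁻⁹ in the test suite, and the suite also
verifies that 1.001 × rate* violates a constraint. RCRs are maximized
unrounded; rounding is display-only (half away from zero, 3 decimals for
RCRs), which reproduces the published rates at their printed precision.
Tractor and hand-held rates are maximized independently, as the published
combined-task table reports them. Seed-treatment loading and bagging do
not scale with the application rate (fixed daily amount; concentration
banding), so GES2 rate maximization is meaningful only for the dispersal
group.

If no constraint has a positive slope (no exposure pathway at all) the
maximizer reports the group as unbounded rather than inventing a rate.

## Numerical and design choices

- All intermediate quantities are carried at full double precision;
  rounding happens only at display/serialization. This reproduces every
  published row, including three table entries that are *not* consistent
  with arithmetic on their rounded neighbours.
- Dermal PPE factors (gloves 10, coverall 5) apply multiplicatively to the
  whole-body estimate — the screening simplification; per-body-part splits
  are out of scope. RPE divides inhalation by 10 or 20. Applying
  protection twice is an error (estimates record their protection state).
- The registry is immutable during a run, fully serializable to YAML (one
  entry per constant with value and source), and overridable by a partial
  YAML document that is merged and re-validated. The volatility threshold
  is pinned at exactly 0.1 Pa by a validity check.
- The synthetic-substance generator used in the property tests spreads
  vapour pressures log-uniformly across the 0.1 Pa threshold and spreads
  DNEL ratios so that different constraints bind, including one substance
  whose general-population DNELs force the bystander constraint to bind.
  It emulates the *inputs* a registrant might bring, not measured exposure
  variability: passing property tests demonstrates internal consistency
  of the algebra, not field accuracy of the surrogate data.

## Worked reference run

```{r}
reg <- default_registry()
subst <- substance("reference co-formulant", "solid", 0.001,
                   dnel_worker_dermal = 3, dnel_worker_inhalation = 11,
                   dnel_general_dermal = 1.5, dnel_general_inhalation = 2.6)
res <- run_full_assessment(
  assessment_request(subst, mode = "maximize", target_rcr = 0.9, reg = reg)
)
res
res$max_use_rates
worst_case(res$ges1$ml)[, c("equipment", "formulation", "dermal",
                            "inhalation", "rcr_total")]
```

## Known limitations

- GES2/GES3/GES4 absolute values rest on placeholder surrogates until the
  PHED/TRA/SOPREA constants are supplied through a registry override.
- No resident (long-term) bystander scenario, no multi-day residue
  dissipation beyond the two-application assumption, no aggregate
  consumer-plus-worker exposure, no route-to-route extrapolation.
- Dermal predictions for volatile co-formulants are conservative:
  volatilization from spray mist and from skin is not credited.
- The optional area-based dermal DNEL (mg/cm²) is carried on the substance
  but no worked example constrains that pathway.
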