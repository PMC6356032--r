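# Shared fixtures: the reference substance behind the published screening
# tables (solid, 0.001 Pa, worker DNELs 3 dermal / 11 inhalation, general
# DNELs 1.5 / 2.6), and the effective rates that make the table rows
# mutually consistent.

# internal registry accessor used by a few calibration checks
ue_value <- function(...) owbscreen:::ue_value(...)

reference_substance <- function(vapour_pressure = 0.001,
                                physical_state = "solid") {
  substance("reference", physical_state, vapour_pressure,
            dnel_worker_dermal = 3, dnel_worker_inhalation = 11,
            dnel_general_dermal = 1.5, dnel_general_inhalation = 2.6)
}

RATE_TRACTOR <- 1.156    # kg/ha (23.12 kg/day over 20 ha)
RATE_HANDHELD <- 0.768   # kg/ha (1 ha/day)

# Published geometric-mean rows: exposures at the group rates, with the
# printed total RCRs. Used for round-trip and RCR-arithmetic checks.
published_ml_rows <- function() {
  data.frame(
    technique = rep(c("boom", "airblast", "handheld"), each = 3),
    formulation = rep(c("liquid", "WP", "WG"), 3),
    dermal = c(0.793, 1.982, 0.661, 0.317, 0.793, 0.264,
               2.249, 0.549, 0.230),
    inhalation = c(0.0014, 0.1618, 0.0185, 0.0006, 0.0647, 0.0074,
                   0.0038, 0.0614, 0.0015),
    rcr_total = c(0.264, 0.675, 0.222, 0.106, 0.270, 0.089,
                  0.750, 0.189, 0.077),
    stringsAsFactors = FALSE
  )
}

published_app_rows <- function() {
  data.frame(
    technique = c("boom", "airblast", "handheld", "handheld"),
    environment = c("outdoor", "outdoor", "outdoor", "indoor"),
    dermal = c(0.674, 1.519, 0.443, 0.443),
    inhalation = c(0.0023, 0.0166, 0.0230, 0.0230),
    rcr_total = c(0.225, 0.508, 0.150, 0.150),
    stringsAsFactors = FALSE
  )
}
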