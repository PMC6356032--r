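# GES1 indirect-exposure extensions: worker re-entry into treated crops and
# bystander exposure to spray drift.

#' Re-entry parameters
#'
#' @param dfr0 Dislodgeable foliar residue per unit application rate,
#'   ug/cm2 per kg/ha per application.
#' @param n_applications Number of applications contributing residue.
#' @param tc Leaf-to-worker transfer coefficient, cm2/h.
#' @param duration Re-entry task duration, h.
#' @param bw Worker body weight, kg.
#' @return An object of class `owb_reentry_params`.
#' @export
reentry_params <- function(dfr0, n_applications = 2, tc, duration, bw = 70) {
  vals <- c(dfr0 = dfr0, tc = tc, duration = duration, bw = bw)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("re-entry parameters must be positive", call. = FALSE)
  }
  if (n_applications < 1 || n_applications != round(n_applications)) {
    stop("n_applications must be a positive integer", call. = FALSE)
  }
  structure(list(dfr0 = dfr0, n_applications = n_applications, tc = tc,
                 duration = duration, bw = bw),
            class = "owb_reentry_params")
}

registry_reentry <- function(reg) {
  rp <- reg$reentry
  reentry_params(rp$dfr0, rp$n_applications, rp$tc, rp$duration, rp$bw)
}

#' Worker re-entry exposure (dermal, via dislodgeable foliar residue)
#'
#' Dermal dose from contact with treated foliage:
#' `DFR0 * n_applications * rate * TC * duration / (bw * 1000)` in
#' mg/kg bw/day. For volatile substances (vapour pressure at or above the
#' registry threshold) the residue is assumed to have evaporated within 24 h
#' and the exposure is zero. Inhalation is not part of this model.
#'
#' @param application_rate kg/ha.
#' @param subst An [substance()].
#' @param rp An [reentry_params()]; defaults to the registry block.
#' @param reg An `owb_registry`.
#' @return An `owb_estimate` (worker population, dermal route only).
#' @export
reentry_exposure <- function(application_rate, subst, rp = NULL,
                             reg = default_registry()) {
  if (application_rate < 0) {
    stop("application rate must be >= 0", call. = FALSE)
  }
  if (is.null(rp)) rp <- registry_reentry(reg)
  dermal <- if (subst$vapour_pressure >= reg$defaults$vp_threshold) {
    0
  } else {
    rp$dfr0 * rp$n_applications * application_rate * rp$tc * rp$duration /
      (rp$bw * 1000)
  }
  exposure_estimate(
    dermal, 0, subst, "worker",
    provenance = list(model = "re-entry (DFR/TC)",
                      application_rate = application_rate)
  )
}

#' Bystander parameters
#'
#' @param drift_fraction Fraction of the application rate deposited at the
#'   bystander's position, in (0, 1).
#' @param exposed_area Exposed body surface, cm2.
#' @param bw Body weight, kg (general population adult).
#' @param inhalation_unit_exposure mg airborne per kg of substance handled.
#' @param breathing_rate m3/h.
#' @param duration Time spent near the treated field, h.
#' @param vapour_coeff Additional vapour concentration per unit rate for
#'   volatile substances, mg/m3 per kg/ha.
#' @return An object of class `owb_bystander_params`.
#' @export
bystander_params <- function(drift_fraction, exposed_area, bw = 60,
                             inhalation_unit_exposure, breathing_rate,
                             duration, vapour_coeff = 0) {
  if (drift_fraction <= 0 || drift_fraction >= 1) {
    stop("drift_fraction must lie in (0, 1)", call. = FALSE)
  }
  vals <- c(exposed_area, bw, inhalation_unit_exposure, breathing_rate,
            duration)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("bystander parameters must be positive", call. = FALSE)
  }
  structure(list(drift_fraction = drift_fraction,
                 exposed_area = exposed_area, bw = bw,
                 inhalation_unit_exposure = inhalation_unit_exposure,
                 breathing_rate = breathing_rate, duration = duration,
                 vapour_coeff = vapour_coeff),
            class = "owb_bystander_params")
}

registry_bystander <- function(reg) {
  bp <- reg$bystander
  bystander_params(bp$drift_fraction, bp$exposed_area, bp$bw,
                   bp$inhalation_unit_exposure, bp$breathing_rate,
                   bp$duration, bp$vapour_coeff)
}

#' Bystander exposure to spray drift
#'
#' Dermal: the areal deposit (1 kg/ha = 0.01 mg/cm2, a dimensional
#' identity) times the drift fraction and exposed body area, per body
#' weight. Inhalation: the airborne amount from the drift unit exposure per
#' kg handled on one hectare, diluted over the breathed volume; a vapour
#' term proportional to the rate is added for vapour pressures above the
#' registry threshold. RCRs use the general-population DNELs even though
#' this row sits inside a professional scenario.
#'
#' @param application_rate kg/ha.
#' @param subst An [substance()].
#' @param bp An [bystander_params()]; defaults to the registry block.
#' @param reg An `owb_registry`.
#' @return An `owb_estimate` (general population).
#' @export
bystander_exposure <- function(application_rate, subst, bp = NULL,
                               reg = default_registry()) {
  if (application_rate < 0) {
    stop("application rate must be >= 0", call. = FALSE)
  }
  if (is.null(bp)) bp <- registry_bystander(reg)
  deposit <- application_rate * 0.01  # mg/cm2 per kg/ha
  dermal <- deposit * bp$drift_fraction * bp$exposed_area / bp$bw
  inhal <- bp$inhalation_unit_exposure * application_rate /
    (bp$breathing_rate * bp$duration)
  if (subst$vapour_pressure > reg$defaults$vp_threshold) {
    inhal <- inhal + bp$vapour_coeff * application_rate
  }
  exposure_estimate(
    dermal, inhal, subst, "general",
    provenance = list(model = "bystander spray drift",
                      application_rate = application_rate)
  )
}
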