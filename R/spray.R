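# GES1: BBA-based mixing/loading and spray application for the three
# techniques and formulation types, with the greenhouse vapour extension.

#' Greenhouse air-exchange parameters for the vapour model
#'
#' @param q Air changes per hour (1/h).
#' @param h Greenhouse height, m.
#' @param tr Duration of substance release to air, h.
#' @param t Worker exposure time, h; must not exceed `tr` (the model covers
#'   the release phase only).
#' @param T Averaging period of the TWA, h.
#' @param V Greenhouse air volume, m3 — informational only; the geometry
#'   enters through the height.
#' @return An object of class `owb_greenhouse`.
#' @export
greenhouse_params <- function(q, h, tr, t, T, V = NA_real_) {
  vals <- c(q = q, h = h, tr = tr, t = t, T = T)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("greenhouse parameters q, h, tr, t, T must be positive",
         call. = FALSE)
  }
  if (t > tr) {
    stop("worker exposure time t must not exceed release duration tr",
         call. = FALSE)
  }
  structure(list(q = q, h = h, tr = tr, t = t, T = T, V = V),
            class = "owb_greenhouse")
}

registry_greenhouse <- function(reg) {
  gp <- reg$greenhouse
  greenhouse_params(gp$q, gp$h, gp$tr, gp$t, gp$T, gp$V)
}

#' Time-weighted average vapour concentration in a greenhouse
#'
#' Constant-rate-release, well-mixed single-zone model: the applied amount
#' vaporises at a constant rate over the release duration into the air
#' column above one hectare (height `h`), with first-order removal by
#' ventilation. The T-hour TWA is
#' \deqn{\mathrm{TWA} = \frac{1}{T}\left(\frac{AR\,t}{q\,h\,t_r}
#'   + \frac{AR\,e^{-qt}}{q^2 h\,t_r} - \frac{AR}{q^2 h\,t_r}\right)\times 100}
#' with the factor 100 converting kg ha^-1 m^-1 to mg m^-3.
#'
#' @param application_rate Substance application rate, kg/ha.
#' @param gp An [greenhouse_params()].
#' @return TWA concentration, mg/m3. Linear in the application rate.
#' @export
crrm_twa <- function(application_rate, gp) {
  stopifnot(inherits(gp, "owb_greenhouse"))
  if (application_rate < 0) {
    stop("application rate must be >= 0", call. = FALSE)
  }
  ar <- application_rate
  # expm1 regroups the e^(-qt) - 1 difference; algebraically identical to
  # the printed form, numerically stable for small air-change rates
  base <- ar * gp$t / (gp$q * gp$h * gp$tr) +
    ar * expm1(-gp$q * gp$t) / (gp$q^2 * gp$h * gp$tr)
  base * 100 / gp$T
}

#' Spray scenario description
#'
#' @param technique `"boom"`, `"airblast"` or `"handheld"`.
#' @param formulation `"liquid"`, `"WP"` or `"WG"` (mixing/loading only;
#'   application exposure is formulation-independent because dilution in
#'   water occurs before spraying).
#' @param application_rate Substance application rate, kg/ha.
#' @param environment `"outdoor"` or `"indoor"`; indoor is valid only for
#'   hand-held high-target application.
#' @param prot An [protection()].
#' @return An object of class `owb_spray_scenario`.
#' @export
spray_scenario <- function(technique, formulation = "liquid",
                           application_rate,
                           environment = c("outdoor", "indoor"),
                           prot = protection()) {
  environment <- match.arg(environment)
  if (!technique %in% c("boom", "airblast", "handheld")) {
    stop("unknown spray technique '", technique, "'", call. = FALSE)
  }
  if (!formulation %in% c("liquid", "WP", "WG")) {
    stop("unknown formulation '", formulation, "'", call. = FALSE)
  }
  if (application_rate < 0) {
    stop("application rate must be >= 0", call. = FALSE)
  }
  if (environment == "indoor" && technique != "handheld") {
    stop("indoor application is only valid for hand-held high-target ",
         "spraying", call. = FALSE)
  }
  structure(list(technique = technique, formulation = formulation,
                 application_rate = application_rate,
                 environment = environment, prot = prot),
            class = "owb_spray_scenario")
}

ml_task_for <- function(technique) {
  switch(technique,
         boom = "ml_boom", airblast = "ml_airblast",
         handheld = "ml_handheld")
}

app_task_for <- function(technique) {
  switch(technique,
         boom = "app_boom", airblast = "app_airblast",
         handheld = "app_handheld_high")
}

# Shared unit-exposure algebra: E_dermal = UE_d * Q / bw,
# E_inhal = UE_i * Q / breathing volume, Q = rate * daily area.
ue_exposure <- function(task_id, formulation, daily_amount, subst, reg,
                        percentile = "geometric_mean",
                        bw = reg$defaults$bw_worker,
                        population = "worker", provenance = list()) {
  ue_d <- ue_value(reg, task_id, formulation, "dermal", percentile)
  ue_i <- ue_value(reg, task_id, formulation, "inhalation", percentile)
  exposure_estimate(
    dermal = ue_d * daily_amount / bw,
    inhalation = ue_i * daily_amount / reg$defaults$breathing_volume_workday,
    subst = subst, population = population,
    provenance = c(provenance,
                   list(task = task_id, formulation = formulation,
                        daily_amount = daily_amount, percentile = percentile))
  )
}

#' Mixing and loading exposure for spray applications
#'
#' Material transfer from the container to the receiving vessel, predicted
#' with BBA geometric-mean unit exposures. The daily amount handled is the
#' application rate times the technique's daily treated area.
#'
#' @param scenario An [spray_scenario()].
#' @param subst An [substance()].
#' @param reg An `owb_registry`.
#' @return An `owb_estimate` (worker population, protection applied).
#' @export
ml_spray_exposure <- function(scenario, subst, reg) {
  stopifnot(inherits(scenario, "owb_spray_scenario"))
  tech <- technique_spec(reg, scenario$technique)
  if (!scenario$formulation %in%
      strsplit(tech$allowed_formulations, "|", fixed = TRUE)[[1]]) {
    stop("formulation '", scenario$formulation,
         "' not available for technique '", scenario$technique, "'",
         call. = FALSE)
  }
  q_daily <- scenario$application_rate * tech$area_per_day
  est <- ue_exposure(
    ml_task_for(scenario$technique), scenario$formulation, q_daily,
    subst, reg,
    provenance = list(model = "BBA mixing/loading",
                      technique = scenario$technique)
  )
  apply_protection(est, scenario$prot, reg)
}

#' Spray application exposure
#'
#' Aerosol exposure during spraying, independent of the initial formulation
#' type. For indoor (greenhouse) hand-held application of a volatile
#' substance (vapour pressure above the registry threshold), the
#' constant-rate-release vapour TWA is added to the inhalation route.
#'
#' @inheritParams ml_spray_exposure
#' @param gp Greenhouse parameters; defaults to the registry block. Required
#'   when the scenario is indoor.
#' @return An `owb_estimate` (worker population, protection applied).
#' @export
application_spray_exposure <- function(scenario, subst, reg, gp = NULL) {
  stopifnot(inherits(scenario, "owb_spray_scenario"))
  tech <- technique_spec(reg, scenario$technique)
  if (scenario$environment == "indoor") {
    if (scenario$technique != "handheld") {
      stop("indoor application requires the hand-held technique",
           call. = FALSE)
    }
    if (is.null(gp)) gp <- registry_greenhouse(reg)
  }
  q_daily <- scenario$application_rate * tech$area_per_day
  est <- ue_exposure(
    app_task_for(scenario$technique), "n/a", q_daily, subst, reg,
    provenance = list(model = "BBA application",
                      technique = scenario$technique,
                      environment = scenario$environment)
  )
  if (scenario$environment == "indoor" &&
      subst$vapour_pressure > reg$defaults$vp_threshold) {
    est <- exposure_estimate(
      est$dermal,
      est$inhalation + crrm_twa(scenario$application_rate, gp),
      subst, est$population,
      provenance = c(est$provenance, list(vapour_model = "CRRM TWA"))
    )
  }
  apply_protection(est, scenario$prot, reg)
}

#' Enumerate the GES1 contributing scenarios
#'
#' Computes every technique-by-formulation mixing/loading permutation and
#' every technique-by-environment application permutation at the group
#' rates, and flags the worst case (highest total RCR) separately for the
#' tractor and hand-held groups, in canonical enumeration order with the
#' first maximum winning ties.
#'
#' @param subst An [substance()].
#' @param rate_tractor,rate_handheld Application rates, kg/ha, for the
#'   tractor-mounted and hand-held technique groups.
#' @param prot An [protection()] applied to every permutation.
#' @param reg An `owb_registry`.
#' @return List with `ml` and `application` scenario results.
#' @export
ges1_enumerate <- function(subst, rate_tractor, rate_handheld,
                           prot = protection(), reg = default_registry()) {
  if (rate_tractor < 0 || rate_handheld < 0) {
    stop("application rates must be >= 0", call. = FALSE)
  }
  techniques <- c("boom", "airblast", "handheld")
  rate_for <- function(technique) {
    if (technique == "handheld") rate_handheld else rate_tractor
  }
  group_for <- function(technique) {
    if (technique == "handheld") "hand_held" else "tractor"
  }
  equip_ml <- c(boom = "Mixing and loading, boom sprayer",
                airblast = "Mixing and loading, broadcast air-assisted sprayer",
                handheld = "Mixing and loading, hand-held sprayer")
  equip_app <- c(boom = "Boom spraying",
                 airblast = "Broadcast air-assisted spraying",
                 handheld = "Hand-held spraying, high-level target")

  ml_rows <- list(); ml_ests <- list()
  for (technique in techniques) {
    for (formulation in c("liquid", "WP", "WG")) {
      sc <- spray_scenario(technique, formulation, rate_for(technique),
                           prot = prot)
      est <- ml_spray_exposure(sc, subst, reg)
      key <- paste(technique, formulation, sep = ".")
      ml_ests[[key]] <- est
      ml_rows[[key]] <- estimate_row(est, equip_ml[[technique]], "BBA",
                                     formulation, group_for(technique))
    }
  }

  app_rows <- list(); app_ests <- list()
  for (technique in techniques) {
    envs <- if (technique == "handheld") c("outdoor", "indoor") else "outdoor"
    for (env in envs) {
      sc <- spray_scenario(technique, "liquid", rate_for(technique),
                           environment = env, prot = prot)
      est <- application_spray_exposure(sc, subst, reg)
      key <- paste(technique, env, sep = ".")
      app_ests[[key]] <- est
      label <- if (env == "indoor") {
        paste0(equip_app[[technique]], ", indoors (greenhouse)")
      } else {
        equip_app[[technique]]
      }
      app_rows[[key]] <- estimate_row(est, label, "BBA", "n/a",
                                      group_for(technique), environment = env)
    }
  }

  list(
    ml = scenario_result("PROC 8a: mixing and loading (spray)",
                         ml_rows, ml_ests),
    application = scenario_result("PROC 11: spray application",
                                  app_rows, app_ests)
  )
}
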