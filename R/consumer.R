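# GES3/GES4: amateur spray and granule/seed scenarios adapted from the
# professional models: no PPE available, 60 kg body weight, treated areas
# capped at 200 m2/day, and 75th-percentile unit exposures for spraying.

#' Consumer scenario description
#'
#' @param kind `"spray_handheld"`, `"spread_hand"`, `"spread_push"` or
#'   `"spread_belly"`.
#' @param application_rate kg/ha.
#' @param treated_area ha/day; clamped to the registry consumer area cap
#'   (0.02 ha = 200 m2) at evaluation time.
#' @return An object of class `owb_consumer_scenario`. Consumers have no
#'   protection field: no PPE credit is possible.
#' @export
consumer_scenario <- function(kind, application_rate, treated_area = NULL) {
  if (!kind %in% c("spray_handheld", "spread_hand", "spread_push",
                   "spread_belly")) {
    stop("unknown consumer scenario kind '", kind, "'", call. = FALSE)
  }
  if (application_rate < 0) {
    stop("application rate must be >= 0", call. = FALSE)
  }
  if (!is.null(treated_area) && treated_area <= 0) {
    stop("treated area must be positive", call. = FALSE)
  }
  structure(list(kind = kind, application_rate = application_rate,
                 treated_area = treated_area),
            class = "owb_consumer_scenario")
}

consumer_area <- function(scenario, reg) {
  cap <- reg$defaults$consumer_area_cap
  if (is.null(scenario$treated_area)) cap else min(scenario$treated_area, cap)
}

# Consumers cannot take protection credit; reject any attempt explicitly.
check_no_consumer_ppe <- function(prot) {
  if (!is.null(prot)) {
    if (prot$gloves || prot$coverall || prot$rpe != "none" || prot$lev) {
      stop("no PPE is available to consumers; protection cannot be applied",
           call. = FALSE)
    }
  }
  invisible(NULL)
}

#' Consumer spray exposure (hand-held, 75th percentile)
#'
#' Hand-held mixing/loading plus high-target application algebra with the
#' 75th-percentile unit-exposure series, 60 kg body weight and the 0.02 ha
#' daily area cap. RCRs use the general-population DNELs.
#'
#' @param scenario A [consumer_scenario()] of kind `"spray_handheld"`.
#' @param subst An [substance()].
#' @param reg An `owb_registry`.
#' @param formulation Formulation handled during loading.
#' @param prot Must be absent or all-off; consumers get no protection
#'   credit.
#' @return An `owb_estimate` (general population): loading plus application.
#' @export
consumer_spray_exposure <- function(scenario, subst, reg,
                                    formulation = "liquid", prot = NULL) {
  stopifnot(inherits(scenario, "owb_consumer_scenario"))
  if (scenario$kind != "spray_handheld") {
    stop("consumer_spray_exposure requires kind 'spray_handheld'",
         call. = FALSE)
  }
  check_no_consumer_ppe(prot)
  bw <- reg$defaults$bw_consumer
  q_daily <- scenario$application_rate * consumer_area(scenario, reg)
  ml <- ue_exposure("ml_handheld", formulation, q_daily, subst, reg,
                    percentile = "p75", bw = bw, population = "general",
                    provenance = list(model = "BBA p75 mixing/loading",
                                      consumer = TRUE))
  app <- ue_exposure("app_handheld_high", "n/a", q_daily, subst, reg,
                     percentile = "p75", bw = bw, population = "general",
                     provenance = list(model = "BBA p75 application",
                                       consumer = TRUE))
  combine_estimates(list(ml, app))
}

#' Consumer granule/seed spreading exposure (residential surrogates)
#'
#' Residential spreading unit values (SOPREA-style), 60 kg body weight and
#' the 0.02 ha daily area cap. RCRs use the general-population DNELs.
#'
#' @param scenario A [consumer_scenario()] with a spreading kind.
#' @inheritParams consumer_spray_exposure
#' @return An `owb_estimate` (general population).
#' @export
consumer_solid_exposure <- function(scenario, subst, reg, prot = NULL) {
  stopifnot(inherits(scenario, "owb_consumer_scenario"))
  if (!scenario$kind %in% c("spread_hand", "spread_push", "spread_belly")) {
    stop("consumer_solid_exposure requires a spreading kind", call. = FALSE)
  }
  check_no_consumer_ppe(prot)
  task_id <- paste0("soprea_", scenario$kind)
  bw <- reg$defaults$bw_consumer
  q_daily <- scenario$application_rate * consumer_area(scenario, reg)
  ue_exposure(task_id, "granule", q_daily, subst, reg,
              percentile = "p75", bw = bw, population = "general",
              provenance = list(model = "residential spreading surrogate",
                                consumer = TRUE))
}
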