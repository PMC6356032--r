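# GES2: professional seed-treatment loading, treated-seed bagging, and
# granule / treated-seed loading and dispersal via PHED surrogate unit
# exposures. Working clothes are inherent in the surrogate values; granules
# and treated seeds are taken as non-volatile, so no indoor vapour term.

PHED_TASKS <- c("load_granule_tractor", "spread_tractor", "spread_belly",
                "spread_push", "spread_hand")
SEEDTREAT_TASKS <- c("load_seedtreat_liquid", "load_seedtreat_wp")

#' Solid-handling scenario description
#'
#' @param task One of the seed-treatment loading tasks
#'   (`"load_seedtreat_liquid"`, `"load_seedtreat_wp"`),
#'   `"bag_treated_seeds"`, or a granule/seed dispersal task
#'   (`"load_granule_tractor"`, `"spread_tractor"`, `"spread_belly"`,
#'   `"spread_push"`, `"spread_hand"`).
#' @param application_rate kg/ha; required for dispersal tasks.
#' @param concentration Substance mass fraction in the treated seeds, in
#'   (0, 1]; required for bagging.
#' @param daily_amount Optional kg/day override for seed-treatment loading;
#'   defaults to the registry value.
#' @param lev Local exhaust ventilation flag (bagging only).
#' @param prot An [protection()].
#' @return An object of class `owb_solid_scenario`.
#' @export
solid_scenario <- function(task, application_rate = NULL,
                           concentration = NULL, daily_amount = NULL,
                           lev = FALSE, prot = protection()) {
  known <- c(SEEDTREAT_TASKS, "bag_treated_seeds", PHED_TASKS)
  if (!task %in% known) {
    stop("unknown solid-handling task '", task, "'", call. = FALSE)
  }
  if (task == "bag_treated_seeds") {
    if (is.null(concentration) || concentration <= 0 || concentration > 1) {
      stop("bagging requires a concentration in (0, 1]", call. = FALSE)
    }
  }
  if (task %in% PHED_TASKS) {
    if (is.null(application_rate) || application_rate < 0) {
      stop("dispersal tasks require an application rate >= 0", call. = FALSE)
    }
  }
  structure(list(task = task, application_rate = application_rate,
                 concentration = concentration, daily_amount = daily_amount,
                 lev = isTRUE(lev), prot = prot),
            class = "owb_solid_scenario")
}

phed_technique_for <- function(task) {
  switch(task,
         load_granule_tractor = "spreader_tractor",
         spread_tractor = "spreader_tractor",
         spread_belly = "spreader_belly",
         spread_push = "spreader_push",
         spread_hand = "spreader_hand")
}

#' Granule and treated-seed handling exposure (PHED surrogates)
#'
#' Same unit-exposure algebra as the spray models, with PHED surrogate
#' values. Loading of hand-held equipment (belly grinder, push spreader)
#' cannot be estimated separately and is implicit in the dispersal values;
#' requesting it raises an error pointing to the combined task.
#'
#' @param scenario An [solid_scenario()] with a PHED task.
#' @param subst An [substance()].
#' @param reg An `owb_registry`.
#' @return An `owb_estimate` (worker population).
#' @export
phed_exposure <- function(scenario, subst, reg) {
  stopifnot(inherits(scenario, "owb_solid_scenario"))
  if (scenario$task %in% c("load_spread_belly", "load_spread_push",
                           "load_spread_hand")) {
    stop("loading of hand-held spreading equipment cannot be estimated ",
         "separately; use the combined dispersal task", call. = FALSE)
  }
  if (!scenario$task %in% PHED_TASKS) {
    stop("'", scenario$task, "' is not a PHED task", call. = FALSE)
  }
  tech <- technique_spec(reg, phed_technique_for(scenario$task))
  q_daily <- scenario$application_rate * tech$area_per_day
  est <- ue_exposure(
    paste0("phed_", scenario$task), "granule", q_daily, subst, reg,
    provenance = list(model = "PHED surrogate", task = scenario$task)
  )
  apply_protection(est, scenario$prot, reg)
}

#' Seed-treatment loading exposure (BBA tractor-tank analogue)
#'
#' Transfer of concentrated product into the seed-treatment process tank,
#' assessed with the boom-sprayer loading unit exposures for liquid or WP
#' formulations and a registry-defined daily amount handled.
#'
#' @param scenario An [solid_scenario()] with a seed-treatment loading task.
#' @inheritParams phed_exposure
#' @return An `owb_estimate` (worker population).
#' @export
seedtreat_loading_exposure <- function(scenario, subst, reg) {
  stopifnot(inherits(scenario, "owb_solid_scenario"))
  if (!scenario$task %in% SEEDTREAT_TASKS) {
    stop("granule formulations have no BBA loading analogue; ",
         "seed-treatment loading covers liquid and WP only", call. = FALSE)
  }
  task_id <- if (scenario$task == "load_seedtreat_liquid") {
    "seedtreat_load_liquid"
  } else {
    "seedtreat_load_wp"
  }
  formulation <- if (scenario$task == "load_seedtreat_liquid") "liquid"
                 else "WP"
  q_daily <- scenario$daily_amount
  if (is.null(q_daily)) q_daily <- reg$seedtreat$daily_amount
  est <- ue_exposure(
    task_id, formulation, q_daily, subst, reg,
    provenance = list(model = "BBA loading analogue (seed treatment)",
                      task = scenario$task)
  )
  apply_protection(est, scenario$prot, reg)
}

bagging_conc_factor <- function(reg, concentration) {
  bands <- reg$bagging$conc_bands
  idx <- which(concentration <= bands$max_conc)[1]
  if (is.na(idx)) {
    stop("no concentration band registered for concentration ",
         concentration, call. = FALSE)
  }
  bands$factor[idx]
}

bagging_band_for <- function(reg, subst, dustiness = NULL) {
  if (subst$physical_state == "solid") {
    if (is.null(dustiness)) dustiness <- reg$bagging$default_dustiness
    dustiness
  } else {
    brk <- reg$bagging$vp_band_breaks
    if (subst$vapour_pressure < brk[1]) "low"
    else if (subst$vapour_pressure <= brk[2]) "medium"
    else "high"
  }
}

#' Treated-seed bagging exposure (full-shift transfer surrogates)
#'
#' Full-shift dermal and inhalation surrogate values looked up by physical
#' state and band (dustiness for solids, vapour-pressure band for liquids),
#' scaled by the concentration-band factor. Local exhaust ventilation
#' reduces the inhalation route by the registry LEV reduction. Independent
#' of application rate.
#'
#' @param scenario An [solid_scenario()] with task `"bag_treated_seeds"`.
#' @inheritParams phed_exposure
#' @param dustiness Optional dustiness band override for solids
#'   (`"low"`, `"medium"`, `"high"`).
#' @return An `owb_estimate` (worker population).
#' @export
bagging_exposure <- function(scenario, subst, reg, dustiness = NULL) {
  stopifnot(inherits(scenario, "owb_solid_scenario"))
  if (scenario$task != "bag_treated_seeds") {
    stop("bagging_exposure requires task 'bag_treated_seeds'", call. = FALSE)
  }
  band <- bagging_band_for(reg, subst, dustiness)
  tab <- reg$bagging$table
  hit <- tab$state == subst$physical_state & tab$band == band
  if (!any(hit)) {
    stop("no bagging surrogate registered for state '",
         subst$physical_state, "', band '", band, "'", call. = FALSE)
  }
  f <- bagging_conc_factor(reg, scenario$concentration)
  prot <- scenario$prot
  prot$lev <- scenario$lev || prot$lev
  est <- exposure_estimate(
    tab$dermal[hit] * f, tab$inhalation[hit] * f, subst, "worker",
    provenance = list(model = "full-shift transfer surrogate (bagging)",
                      band = band, concentration = scenario$concentration)
  )
  apply_protection(est, prot, reg, lev_supported = TRUE)
}

#' Enumerate the GES2 contributing scenarios
#'
#' Seed-treatment loading (PROC 8a), treated-seed bagging (PROC 8b) and
#' granule/seed dispersal (PROC 8a) permutation tables, each with its worst
#' case flagged. The correlation structure is recorded explicitly: loading
#' of seed-treatment product pairs with bagging, and dispersal loading pairs
#' with spreading; the two groups are performed by different individuals and
#' are never combined.
#'
#' @param subst An [substance()].
#' @param rate Application rate for the dispersal tasks, kg/ha.
#' @param concentration Substance concentration in treated seeds, (0, 1].
#' @param prot An [protection()].
#' @param lev Local exhaust ventilation for bagging.
#' @param reg An `owb_registry`.
#' @return List with scenario results `loading`, `bagging`, `dispersal` and
#'   the `correlated_pairs` ledger.
#' @export
ges2_enumerate <- function(subst, rate, concentration, prot = protection(),
                           lev = FALSE, reg = default_registry()) {
  load_rows <- list(); load_ests <- list()
  for (task in SEEDTREAT_TASKS) {
    sc <- solid_scenario(task, prot = prot)
    est <- seedtreat_loading_exposure(sc, subst, reg)
    formulation <- if (task == "load_seedtreat_liquid") "liquid" else "WP"
    load_ests[[task]] <- est
    load_rows[[task]] <- estimate_row(
      est, "Loading of seed treatment equipment", "BBA analogue",
      formulation, "seed_treatment"
    )
  }
  sc_load_gran <- solid_scenario("load_granule_tractor",
                                 application_rate = rate, prot = prot)
  est <- phed_exposure(sc_load_gran, subst, reg)
  load_ests$load_granule_tractor <- est
  load_rows$load_granule_tractor <- estimate_row(
    est, "Loading of tractor-mounted broadcast spreader", "PHED",
    "granule", "dispersal"
  )

  sc_bag <- solid_scenario("bag_treated_seeds", concentration = concentration,
                           lev = lev, prot = prot)
  bag_est <- bagging_exposure(sc_bag, subst, reg)
  bag_rows <- list(bag = estimate_row(
    bag_est, "Transfer of treated seeds into bags", "TRA surrogate",
    "seed", "seed_treatment"
  ))

  disp_rows <- list(); disp_ests <- list()
  disp_tasks <- c("spread_tractor", "spread_belly", "spread_push",
                  "spread_hand")
  disp_labels <- c(
    spread_tractor = "Tractor-mounted broadcast spreading",
    spread_belly = "Mechanical spreading, belly grinder",
    spread_push = "Mechanical spreading, push rotary spreader",
    spread_hand = "Manual spreading by hand"
  )
  for (task in disp_tasks) {
    sc <- solid_scenario(task, application_rate = rate, prot = prot)
    est <- phed_exposure(sc, subst, reg)
    disp_ests[[task]] <- est
    disp_rows[[task]] <- estimate_row(est, disp_labels[[task]], "PHED",
                                      "granule", "dispersal")
  }

  list(
    loading = scenario_result("PROC 8a: mixing and loading (seed/granule)",
                              load_rows, load_ests),
    bagging = scenario_result("PROC 8b: transfer of treated seeds",
                              bag_rows, list(bag = bag_est)),
    dispersal = scenario_result("PROC 8a: delivery and dispersal",
                                disp_rows, disp_ests),
    correlated_pairs = list(
      c("seed_treatment_loading", "bagging"),
      c("dispersal_loading", "spreading")
    )
  )
}
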