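# Parameter registry: every model constant with provenance, plus the
# calibration routine that back-derives unit exposures from published
# screening-table anchor rows.

#' Back-derive a unit exposure from a route-specific exposure
#'
#' The BBA-style exposure algebra is `E = UE * Q / reference`, where `Q` is
#' the amount of substance handled per day (kg) and `reference` is the worker
#' body weight (kg, dermal route) or the breathing volume per work day (m3,
#' inhalation route). Given a published exposure `E` at a known `Q`, the unit
#' exposure in mg per kg of substance handled is recovered by inverting that
#' relation.
#'
#' @param printed_exposure Route-specific exposure: mg/kg bw/day (dermal) or
#'   mg/m3 (inhalation). Must be non-negative.
#' @param daily_amount Amount of substance handled, kg/day. Must be positive.
#' @param reference Body weight in kg (dermal) or breathing volume in m3
#'   (inhalation). Must be positive.
#' @return Unit exposure, mg per kg of substance handled.
#' @examples
#' calibrate_unit_exposure(0.793, 23.12, 70)   # dermal, boom loading, liquid
#' calibrate_unit_exposure(0.1618, 23.12, 10)  # inhalation, boom loading, WP
#' @export
calibrate_unit_exposure <- function(printed_exposure, daily_amount, reference) {
  if (!is.numeric(printed_exposure) || any(printed_exposure < 0)) {
    stop("`printed_exposure` must be non-negative", call. = FALSE)
  }
  if (!is.numeric(daily_amount) || any(daily_amount <= 0)) {
    stop("`daily_amount` must be positive", call. = FALSE)
  }
  if (!is.numeric(reference) || any(reference <= 0)) {
    stop("`reference` must be positive", call. = FALSE)
  }
  printed_exposure * reference / daily_amount
}

# Published anchor rows (geometric-mean exposures at the daily amounts
# behind them) used to calibrate the spray unit exposures. Daily amounts:
# 23.12 kg/day (boom, 20 ha at 1.156 kg/ha), 0.768 kg/day (hand-held, 1 ha
# at 0.768 kg/ha). The air-assisted loading rows share the tractor loading
# unit exposures (verified against the published rows at 9.25 kg/day);
# air-assisted application has its own unit exposure anchored at 9.25 kg/day.
owb_anchor_rows <- function() {
  data.frame(
    task_id     = c(rep("ml_boom", 3), rep("ml_handheld", 3),
                    "app_boom", "app_airblast", "app_handheld_high"),
    formulation = c("liquid", "WP", "WG", "liquid", "WP", "WG",
                    "n/a", "n/a", "n/a"),
    dermal      = c(0.793, 1.982, 0.661, 2.249, 0.549, 0.230,
                    0.674, 1.519, 0.443),
    inhalation  = c(0.0014, 0.1618, 0.0185, 0.0038, 0.0614, 0.0015,
                    0.0023, 0.0166, 0.0230),
    daily_amount = c(rep(23.12, 3), rep(0.768, 3), 23.12, 9.25, 0.768),
    stringsAsFactors = FALSE
  )
}

# Unit-exposure table built from the anchors plus surrogate blocks.
build_unit_exposures <- function(bw_worker = 70, breathing_volume = 10) {
  an <- owb_anchor_rows()
  gm <- data.frame(
    task_id     = rep(an$task_id, 2),
    formulation = rep(an$formulation, 2),
    route       = rep(c("dermal", "inhalation"), each = nrow(an)),
    value       = c(
      calibrate_unit_exposure(an$dermal, an$daily_amount, bw_worker),
      calibrate_unit_exposure(an$inhalation, an$daily_amount, breathing_volume)
    ),
    percentile  = "geometric_mean",
    source      = "calibrated from published BBA screening-table rows",
    stringsAsFactors = FALSE
  )

  # Air-assisted loading shares the tractor (boom) loading unit exposures.
  ab <- gm[gm$task_id == "ml_boom", ]
  ab$task_id <- "ml_airblast"
  ab$source <- "tractor loading unit exposures (shared with boom)"

  # Seed-treatment loading reuses the boom loading analogues (liquid, WP).
  st <- gm[gm$task_id == "ml_boom" & gm$formulation %in% c("liquid", "WP"), ]
  st$task_id <- ifelse(st$formulation == "liquid",
                       "seedtreat_load_liquid", "seedtreat_load_wp")
  st$source <- "BBA tractor-tank loading analogue"

  # PHED surrogate unit exposures for granule / treated-seed handling.
  # The published surrogate table was not transcribed; these are synthetic
  # placeholder values of plausible magnitude, flagged as such.
  phed <- data.frame(
    task_id = rep(c("phed_load_granule_tractor", "phed_spread_tractor",
                    "phed_spread_belly", "phed_spread_push",
                    "phed_spread_hand"), 2),
    formulation = "granule",
    route = rep(c("dermal", "inhalation"), each = 5),
    value = c(0.090, 0.011, 0.500, 0.250, 1.900,
              0.0011, 0.0006, 0.0060, 0.0020, 0.0040),
    percentile = "geometric_mean",
    source = "synthetic placeholder (PHED surrogate table)",
    stringsAsFactors = FALSE
  )

  # 75th-percentile series for the consumer spray scenarios: a distinct
  # percentile series, not a scalar multiplier on the geometric means.
  # Synthetic placeholder values, each above the geometric-mean entry.
  p75 <- data.frame(
    task_id = rep(c("ml_handheld", "ml_handheld", "ml_handheld",
                    "app_handheld_high"), 2),
    formulation = rep(c("liquid", "WP", "WG", "n/a"), 2),
    route = rep(c("dermal", "inhalation"), each = 4),
    value = c(430, 105, 44, 85,
              0.104, 1.68, 0.041, 0.63),
    percentile = "p75",
    source = "synthetic placeholder (75th percentile series)",
    stringsAsFactors = FALSE
  )

  # SOPREA-style consumer spreading values (p75 by construction).
  soprea <- data.frame(
    task_id = rep(c("soprea_spread_hand", "soprea_spread_push",
                    "soprea_spread_belly"), 2),
    formulation = "granule",
    route = rep(c("dermal", "inhalation"), each = 3),
    value = c(6.0, 1.2, 2.0, 0.012, 0.005, 0.008),
    percentile = "p75",
    source = "synthetic placeholder (SOPREA residential values)",
    stringsAsFactors = FALSE
  )

  out <- rbind(gm, ab, st, phed, p75, soprea)
  rownames(out) <- NULL
  out
}

build_techniques <- function() {
  data.frame(
    technique_id = c("boom", "airblast", "handheld",
                     "spreader_tractor", "spreader_belly",
                     "spreader_push", "spreader_hand"),
    group = c("tractor", "tractor", "hand_held",
              "tractor", "hand_held", "hand_held", "hand_held"),
    area_per_day = c(20, 8, 1, 20, 1, 1, 0.25),
    environments = c("outdoor", "outdoor", "outdoor|indoor",
                     "outdoor", "outdoor", "outdoor", "outdoor"),
    allowed_formulations = c("liquid|WP|WG", "liquid|WP|WG", "liquid|WP|WG",
                             "granule", "granule", "granule", "granule"),
    source = c(rep("daily areas implied by published daily amounts / rates", 3),
               rep("synthetic placeholder (spreading work rates)", 4)),
    stringsAsFactors = FALSE
  )
}

#' Built-in parameter registry
#'
#' Assembles the complete, immutable set of model constants: calibrated and
#' surrogate unit exposures, technique work rates, population defaults,
#' protection factors, and the greenhouse, re-entry, bystander, seed
#' treatment, bagging and consumer parameter blocks. Every entry carries a
#' `source` provenance tag; constants that could not be traced to a published
#' value are tagged as synthetic placeholders.
#'
#' Re-entry and bystander constants are pinned by calibration: structural
#' values (transfer coefficient, task duration, body metrics) are fixed and
#' the remaining free constant (DFR per unit rate; drift fraction and the
#' bystander inhalation unit exposure) back-solved so the published indirect
#' exposure rows reproduce at the tractor effective rate of 1.156 kg/ha.
#'
#' @return An object of class `owb_registry`.
#' @examples
#' reg <- default_registry()
#' reg$defaults$vp_threshold
#' @export
default_registry <- function() {
  defaults <- list(
    bw_worker = 70,                 # kg
    bw_consumer = 60,               # kg
    bw_bystander = 60,              # kg
    breathing_volume_workday = 10,  # m3 inhaled per work day
    vp_threshold = 0.1,             # Pa, volatility cut-off
    consumer_area_cap = 0.02,       # ha/day (200 m2)
    n_applications_reentry = 2,
    display_decimals_rcr = 3
  )

  protection_factors <- list(
    gloves_dermal_pf = 10,
    coverall_dermal_pf = 5,
    rpe_pf_choices = c(1, 10, 20),
    lev_inhalation_reduction = 0.9,
    source = "default protection factor conventions"
  )

  greenhouse <- list(
    q = 1,    # air changes per hour
    h = 4,    # greenhouse height, m
    tr = 8,   # release duration, h
    t = 8,    # worker exposure time, h
    T = 8,    # averaging period, h
    V = NA_real_,  # informational only; height carries the geometry
    source = "synthetic placeholder (low-ventilation worst case)"
  )

  # Re-entry: dermal = DFR0 * n_app * rate * TC * duration / (bw * 1000).
  # DFR0 back-solved so the published row (0.8778 mg/kg bw/day) reproduces
  # at 1.156 kg/ha with TC = 2500 cm2/h, 8 h, 2 applications, 70 kg bw.
  reentry <- list(
    tc = 2500,          # cm2/h, leaf-to-worker transfer coefficient
    duration = 8,       # h
    n_applications = 2,
    bw = 70,            # kg
    calibration_rate = 1.156,  # kg/ha behind the published row
    calibration_dermal = 0.8778,
    source = "calibrated to published re-entry row"
  )
  reentry$dfr0 <- reentry$calibration_dermal * reentry$bw * 1000 /
    (reentry$n_applications * reentry$calibration_rate *
       reentry$tc * reentry$duration)  # ug/cm2 per kg/ha per application

  # Bystander: dermal = rate * 0.01 mg/cm2 per kg/ha * drift * area / bw;
  # inhalation = UE_inh * rate / (breathing_rate * duration) expressed as
  # mg/m3 via the amount drifting from 1 ha. Drift fraction and the
  # inhalation unit exposure are back-solved from the published row
  # (0.1512 mg/kg bw/day; 0.0102 mg/m3) at 1.156 kg/ha.
  bystander <- list(
    exposed_area = 18000,   # cm2, adult whole-body surface
    bw = 60,                # kg, general population adult
    breathing_rate = 1.25,  # m3/h
    duration = 1,           # h spent near the treated field
    vapour_coeff = 0.01,    # mg/m3 per kg/ha add-on for volatile substances
    calibration_rate = 1.156,
    calibration_dermal = 0.1512,
    calibration_inhalation = 0.0102,
    source = "calibrated to published bystander row; vapour term synthetic"
  )
  bystander$drift_fraction <- bystander$calibration_dermal * bystander$bw /
    (bystander$calibration_rate * 0.01 * bystander$exposed_area)
  bystander$inhalation_unit_exposure <-
    bystander$calibration_inhalation * bystander$breathing_rate *
    bystander$duration / bystander$calibration_rate  # mg per kg handled

  seedtreat <- list(
    daily_amount = 10,  # kg substance loaded per day, on-farm treatment
    source = "synthetic placeholder (on-farm seed treatment throughput)"
  )

  # ECETOC-TRA-style full-shift surrogate lookup for bagging treated seeds:
  # state x band base values, scaled by a concentration-band factor and
  # (inhalation) reduced by LEV. Synthetic placeholder values.
  bagging <- list(
    table = data.frame(
      state = rep(c("solid", "liquid"), each = 3),
      band = rep(c("low", "medium", "high"), 2),
      dermal = c(0.07, 0.35, 0.70, 0.07, 0.35, 0.70),       # mg/kg bw/day
      inhalation = c(1.0, 5.0, 10.0, 0.5, 2.5, 7.5),        # mg/m3
      stringsAsFactors = FALSE
    ),
    conc_bands = data.frame(
      max_conc = c(0.01, 0.05, 0.25, 1),
      factor = c(0.1, 0.2, 0.6, 1),
      stringsAsFactors = FALSE
    ),
    default_dustiness = "medium",
    vp_band_breaks = c(10, 1000),  # Pa: < low | medium | high <
    source = "synthetic placeholder (full-shift transfer surrogates)"
  )

  reg <- list(
    unit_exposures = build_unit_exposures(
      bw_worker = defaults$bw_worker,
      breathing_volume = defaults$breathing_volume_workday
    ),
    techniques = build_techniques(),
    defaults = defaults,
    protection_factors = protection_factors,
    greenhouse = greenhouse,
    reentry = reentry,
    bystander = bystander,
    seedtreat = seedtreat,
    bagging = bagging
  )
  class(reg) <- "owb_registry"
  validate_registry(reg)
  reg
}

#' Validate a parameter registry
#'
#' Checks completeness and the registry invariants: unit exposures
#' non-negative and unique per (task, formulation, route, percentile); a p75
#' entry for every geometric-mean entry the consumer scenarios use; positive
#' work rates with hand-held daily areas not exceeding tractor areas;
#' positive defaults with the volatility threshold at exactly 0.1 Pa;
#' protection factors at least 1 with RPE restricted to \{1, 10, 20\}.
#'
#' @param reg An `owb_registry`.
#' @return `reg`, invisibly, if valid; otherwise an error naming the problem.
#' @export
validate_registry <- function(reg) {
  required <- c("unit_exposures", "techniques", "defaults",
                "protection_factors", "greenhouse", "reentry", "bystander",
                "seedtreat", "bagging")
  missing <- setdiff(required, names(reg))
  if (length(missing)) {
    stop("registry is missing block(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }

  ue <- reg$unit_exposures
  need_cols <- c("task_id", "formulation", "route", "value", "percentile",
                 "source")
  if (!all(need_cols %in% names(ue))) {
    stop("unit_exposures must have columns ",
         paste(need_cols, collapse = ", "), call. = FALSE)
  }
  if (any(ue$value < 0)) {
    bad <- ue[ue$value < 0, ][1, ]
    stop("negative unit exposure for task '", bad$task_id, "' (",
         bad$formulation, ", ", bad$route, ")", call. = FALSE)
  }
  key <- paste(ue$task_id, ue$formulation, ue$route, ue$percentile)
  if (anyDuplicated(key)) {
    stop("duplicate unit exposure entry: ", key[duplicated(key)][1],
         call. = FALSE)
  }
  # consumer spray scenarios require a p75 series for the hand-held tasks
  consumer_tasks <- c("ml_handheld", "app_handheld_high")
  for (task in consumer_tasks) {
    gm <- ue[ue$task_id == task & ue$percentile == "geometric_mean", ]
    for (i in seq_len(nrow(gm))) {
      hit <- ue$task_id == task & ue$formulation == gm$formulation[i] &
        ue$route == gm$route[i] & ue$percentile == "p75"
      if (!any(hit)) {
        stop("missing p75 unit exposure for consumer task '", task, "' (",
             gm$formulation[i], ", ", gm$route[i], ")", call. = FALSE)
      }
    }
  }

  tech <- reg$techniques
  if (any(tech$area_per_day <= 0)) {
    stop("technique daily areas must be positive", call. = FALSE)
  }
  hh <- tech$area_per_day[tech$group == "hand_held"]
  tr <- tech$area_per_day[tech$group == "tractor"]
  if (length(hh) && length(tr) && max(hh) > max(tr)) {
    stop("hand-held daily areas must not exceed tractor daily areas",
         call. = FALSE)
  }

  d <- reg$defaults
  pos <- c("bw_worker", "bw_consumer", "bw_bystander",
           "breathing_volume_workday", "vp_threshold", "consumer_area_cap",
           "n_applications_reentry")
  for (k in pos) {
    if (is.null(d[[k]])) stop("defaults missing key '", k, "'", call. = FALSE)
    if (!is.numeric(d[[k]]) || d[[k]] <= 0) {
      stop("default '", k, "' must be positive", call. = FALSE)
    }
  }
  if (d$vp_threshold != 0.1) {
    stop("vp_threshold must be exactly 0.1 Pa", call. = FALSE)
  }

  pf <- reg$protection_factors
  if (pf$gloves_dermal_pf < 1 || pf$coverall_dermal_pf < 1) {
    stop("dermal protection factors must be >= 1", call. = FALSE)
  }
  if (!all(pf$rpe_pf_choices %in% c(1, 10, 20))) {
    stop("RPE protection factors restricted to 1, 10 or 20", call. = FALSE)
  }
  if (pf$lev_inhalation_reduction < 0 || pf$lev_inhalation_reduction >= 1) {
    stop("LEV inhalation reduction must lie in [0, 1)", call. = FALSE)
  }

  gp <- reg$greenhouse
  for (k in c("q", "h", "tr", "t", "T")) {
    if (!is.numeric(gp[[k]]) || gp[[k]] <= 0) {
      stop("greenhouse parameter '", k, "' must be positive", call. = FALSE)
    }
  }
  if (gp$t > gp$tr) {
    stop("greenhouse exposure time t must not exceed release duration tr",
         call. = FALSE)
  }

  if (reg$reentry$n_applications < 1 ||
      reg$reentry$n_applications != round(reg$reentry$n_applications)) {
    stop("re-entry n_applications must be a positive integer", call. = FALSE)
  }
  if (reg$bystander$drift_fraction <= 0 || reg$bystander$drift_fraction >= 1) {
    stop("bystander drift fraction must lie in (0, 1)", call. = FALSE)
  }

  invisible(reg)
}

#' Load a parameter registry
#'
#' With no arguments returns the built-in registry. Given a YAML document,
#' its entries are merged over the built-in values (recursively for the
#' scalar parameter blocks; unit-exposure records replace matching rows or
#' are appended) and the result re-validated, so a run can override any
#' constant while keeping the remainder pinned.
#'
#' @param path Optional path to a YAML override document.
#' @return An `owb_registry`.
#' @export
load_registry <- function(path = NULL) {
  reg <- default_registry()
  if (is.null(path)) {
    return(reg)
  }
  if (!file.exists(path)) {
    stop("registry file not found: ", path, call. = FALSE)
  }
  ov <- yaml::read_yaml(path)
  known <- c("unit_exposures", "techniques", "defaults",
             "protection_factors", "greenhouse", "reentry", "bystander",
             "seedtreat", "bagging")
  unknown <- setdiff(names(ov), known)
  if (length(unknown)) {
    stop("unknown registry block(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  for (block in intersect(names(ov), c("defaults", "protection_factors",
                                       "greenhouse", "reentry", "bystander",
                                       "seedtreat"))) {
    for (k in names(ov[[block]])) {
      if (!k %in% names(reg[[block]])) {
        stop("unknown key '", k, "' in registry block '", block, "'",
             call. = FALSE)
      }
      reg[[block]][[k]] <- ov[[block]][[k]]
    }
  }
  if (!is.null(ov$unit_exposures)) {
    for (rec in ov$unit_exposures) {
      need <- c("task_id", "formulation", "route", "value", "percentile")
      miss <- setdiff(need, names(rec))
      if (length(miss)) {
        stop("unit exposure override missing field(s): ",
             paste(miss, collapse = ", "), call. = FALSE)
      }
      if (is.null(rec$source)) rec$source <- "user override"
      hit <- with(reg$unit_exposures,
                  task_id == rec$task_id & formulation == rec$formulation &
                    route == rec$route & percentile == rec$percentile)
      row <- data.frame(task_id = rec$task_id, formulation = rec$formulation,
                        route = rec$route, value = rec$value,
                        percentile = rec$percentile, source = rec$source,
                        stringsAsFactors = FALSE)
      if (any(hit)) {
        reg$unit_exposures[which(hit), ] <- row
      } else {
        reg$unit_exposures <- rbind(reg$unit_exposures, row)
      }
    }
  }
  if (!is.null(ov$techniques)) {
    for (rec in ov$techniques) {
      if (is.null(rec$technique_id)) {
        stop("technique override missing 'technique_id'", call. = FALSE)
      }
      hit <- reg$techniques$technique_id == rec$technique_id
      if (!any(hit)) {
        stop("unknown technique '", rec$technique_id, "' in override",
             call. = FALSE)
      }
      for (k in setdiff(names(rec), "technique_id")) {
        if (!k %in% names(reg$techniques)) {
          stop("unknown technique field '", k, "'", call. = FALSE)
        }
        reg$techniques[which(hit), k] <- rec[[k]]
      }
    }
  }
  validate_registry(reg)
  reg
}

#' Serialize a registry to YAML
#'
#' One entry per constant with value and source fields, suitable for editing
#' and re-loading through [load_registry()].
#'
#' @param reg An `owb_registry`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_registry <- function(reg, path) {
  out <- unclass(reg)
  out$unit_exposures <- lapply(seq_len(nrow(reg$unit_exposures)), function(i) {
    as.list(reg$unit_exposures[i, ])
  })
  out$techniques <- lapply(seq_len(nrow(reg$techniques)), function(i) {
    as.list(reg$techniques[i, ])
  })
  out$bagging$table <- lapply(seq_len(nrow(reg$bagging$table)), function(i) {
    as.list(reg$bagging$table[i, ])
  })
  out$bagging$conc_bands <- lapply(
    seq_len(nrow(reg$bagging$conc_bands)),
    function(i) as.list(reg$bagging$conc_bands[i, ])
  )
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}

# Look up one unit exposure value; errors name the missing key.
ue_value <- function(reg, task_id, formulation, route,
                     percentile = "geometric_mean") {
  ue <- reg$unit_exposures
  hit <- ue$task_id == task_id & ue$formulation == formulation &
    ue$route == route & ue$percentile == percentile
  if (sum(hit) != 1) {
    stop("no unit exposure registered for (", task_id, ", ", formulation,
         ", ", route, ", ", percentile, ")", call. = FALSE)
  }
  ue$value[hit]
}

technique_spec <- function(reg, technique_id) {
  hit <- reg$techniques$technique_id == technique_id
  if (!any(hit)) {
    stop("unknown technique '", technique_id, "'", call. = FALSE)
  }
  as.list(reg$techniques[which(hit), ])
}

#' @export
print.owb_registry <- function(x, ...) {
  cat("<owb_registry>\n")
  cat("  unit exposures:", nrow(x$unit_exposures), "entries\n")
  cat("  techniques:    ", nrow(x$techniques), "\n")
  cat("  vp threshold:  ", x$defaults$vp_threshold, "Pa\n")
  cat("  body weights:  ", x$defaults$bw_worker, "kg worker /",
      x$defaults$bw_consumer, "kg consumer\n")
  invisible(x)
}
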