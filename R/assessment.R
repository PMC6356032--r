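# Orchestration: run the generic exposure scenarios, combine correlated
# tasks, maximize the use rate against a target RCR, and assemble the
# reportable result.

#' Build an assessment request
#'
#' @param subst An [substance()].
#' @param mode `"fixed_rate"` or `"maximize"`.
#' @param rates Named list with `tractor` and `hand_held` application rates
#'   (kg/ha); required in fixed-rate mode.
#' @param target_rcr Target total RCR in (0, 1]; required in maximize mode.
#' @param prot A single [protection()] applied to every worker contributing
#'   scenario, or a named list (keys among `ml`, `application`,
#'   `ges2_loading`, `ges2_bagging`, `ges2_dispersal`, `default`).
#' @param concentration Treated-seed substance concentration for GES2.
#' @param lev Local exhaust ventilation for bagging.
#' @param ges Generic exposure scenarios to run, subset of
#'   `c("GES1", "GES2", "GES3", "GES4")`.
#' @param reg An `owb_registry`.
#' @return An object of class `owb_request`.
#' @export
assessment_request <- function(subst, mode = c("fixed_rate", "maximize"),
                               rates = NULL, target_rcr = NULL,
                               prot = protection(), concentration = 0.25,
                               lev = FALSE,
                               ges = c("GES1", "GES2", "GES3", "GES4"),
                               reg = default_registry()) {
  mode <- match.arg(mode)
  if (mode == "maximize") {
    if (is.null(target_rcr) || target_rcr <= 0 || target_rcr > 1) {
      stop("maximize mode requires a target RCR in (0, 1]", call. = FALSE)
    }
  } else {
    if (is.null(rates) || is.null(rates$tractor) || is.null(rates$hand_held)) {
      stop("fixed-rate mode requires rates$tractor and rates$hand_held",
           call. = FALSE)
    }
    if (rates$tractor < 0 || rates$hand_held < 0) {
      stop("application rates must be >= 0", call. = FALSE)
    }
  }
  bad <- setdiff(ges, c("GES1", "GES2", "GES3", "GES4"))
  if (length(bad)) {
    stop("unknown GES selection: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  structure(list(substance = subst, mode = mode, rates = rates,
                 target_rcr = target_rcr, prot = prot,
                 concentration = concentration, lev = lev, ges = ges,
                 registry = reg),
            class = "owb_request")
}

prot_for <- function(request, key) {
  p <- request$prot
  if (inherits(p, "owb_protection")) return(p)
  if (!is.null(p[[key]])) return(p[[key]])
  if (!is.null(p$default)) return(p$default)
  protection()
}

#' Combine the correlated mixing/loading and application tasks
#'
#' Mixing/loading and spraying are carried out in sequence by the same
#' workers, so their exposures add — but per application technique: for each
#' technique the worst formulation loading estimate is combined with that
#' technique's worst application variant, and the group worst case is the
#' technique with the highest combined total. Summing the per-scenario
#' maxima across different techniques would over-predict and is never done.
#'
#' @param ges1 Result of [ges1_enumerate()].
#' @param group `"tractor"` or `"hand_held"`.
#' @return List with `per_technique` (combined `owb_estimate` per
#'   technique), `worst_technique`, and the group's combined `estimate`.
#' @export
combined_correlated <- function(ges1, group = c("tractor", "hand_held")) {
  group <- match.arg(group)
  techniques <- if (group == "tractor") c("boom", "airblast") else "handheld"
  ml_tab <- ges1$ml$table
  app_tab <- ges1$application$table
  if (!nrow(ml_tab) || !any(ml_tab$group == group)) {
    stop("no results available for group '", group, "'", call. = FALSE)
  }
  equip_prefix <- c(boom = "boom", airblast = "airblast",
                    handheld = "handheld")
  per_technique <- list()
  for (technique in techniques) {
    ml_keys <- paste(technique, c("liquid", "WP", "WG"), sep = ".")
    ml_ests <- ges1$ml$estimates[ml_keys]
    ml_best <- ml_ests[[which.max(vapply(ml_ests, function(e) e$rcr_total,
                                         numeric(1)))]]
    app_keys <- grep(paste0("^", equip_prefix[[technique]], "\\."),
                     names(ges1$application$estimates), value = TRUE)
    app_ests <- ges1$application$estimates[app_keys]
    app_best <- app_ests[[which.max(vapply(app_ests,
                                           function(e) e$rcr_total,
                                           numeric(1)))]]
    per_technique[[technique]] <- combine_estimates(list(ml_best, app_best))
  }
  totals <- vapply(per_technique, function(e) e$rcr_total, numeric(1))
  worst <- names(per_technique)[which.max(totals)]
  list(per_technique = per_technique, worst_technique = worst,
       estimate = per_technique[[worst]])
}

# Constraint slopes (total RCR per kg/ha) for one technique group: combined
# correlated tasks per technique, worker re-entry, and bystander drift.
# Every spray model is homogeneous of degree 1 in the rate (including the
# greenhouse vapour term), so slopes are evaluated at a unit probe rate.
group_constraint_slopes <- function(subst, group, prot, reg) {
  probe <- 1
  ges1 <- ges1_enumerate(subst,
                         rate_tractor = if (group == "tractor") probe else 0,
                         rate_handheld = if (group == "hand_held") probe
                                         else 0,
                         prot = prot, reg = reg)
  comb <- combined_correlated(ges1, group)
  slopes <- vapply(comb$per_technique, function(e) e$rcr_total, numeric(1))
  names(slopes) <- paste0("combined_", names(slopes))
  slopes["reentry"] <- reentry_exposure(probe, subst, reg = reg)$rcr_total
  slopes["bystander"] <- bystander_exposure(probe, subst,
                                            reg = reg)$rcr_total
  slopes
}

#' Maximize the substance application rate against a target RCR
#'
#' For each technique group the binding constraint is the largest RCR slope
#' among the combined correlated spray tasks per technique, worker re-entry,
#' and bystander drift (the latter against general-population DNELs). All
#' models are homogeneous of degree 1 in the application rate, so the
#' maximum rate is exactly `target_rcr / max(slope)`; a bisection solver
#' ([maximize_use_rate_bisection()]) cross-checks the closed form.
#'
#' @param subst An [substance()].
#' @param target_rcr Target total RCR in (0, 1].
#' @param prot An [protection()] held fixed during maximization.
#' @param reg An `owb_registry`.
#' @param groups Technique groups to maximize.
#' @return Data frame with one row per group: `group`, `max_rate` (kg/ha),
#'   `binding` (constraint name), `unbounded`. The per-constraint slopes are
#'   attached as the `"slopes"` attribute.
#' @export
maximize_use_rate <- function(subst, target_rcr, prot = protection(),
                              reg = default_registry(),
                              groups = c("tractor", "hand_held")) {
  if (target_rcr <= 0 || target_rcr > 1) {
    stop("target RCR must lie in (0, 1]", call. = FALSE)
  }
  rows <- list()
  all_slopes <- list()
  for (group in groups) {
    slopes <- group_constraint_slopes(subst, group, prot, reg)
    all_slopes[[group]] <- slopes
    if (max(slopes) <= 0) {
      rows[[group]] <- data.frame(group = group, max_rate = NA_real_,
                                  binding = "none (no exposure pathway)",
                                  unbounded = TRUE,
                                  stringsAsFactors = FALSE)
    } else {
      rows[[group]] <- data.frame(
        group = group, max_rate = target_rcr / max(slopes),
        binding = names(slopes)[which.max(slopes)], unbounded = FALSE,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "slopes") <- all_slopes
  out
}

#' Bisection cross-check of the use-rate maximization
#'
#' Solves `max-constraint RCR(rate) = target_rcr` for one group by bisection
#' on the full forward model, independent of the linearity argument used by
#' the closed form.
#'
#' @inheritParams maximize_use_rate
#' @param group Technique group.
#' @param tol Relative tolerance on the bracket width.
#' @return Maximized rate, kg/ha (or `NA` if no constraint ever binds).
#' @export
maximize_use_rate_bisection <- function(subst, target_rcr,
                                        prot = protection(),
                                        reg = default_registry(),
                                        group = "tractor", tol = 1e-12) {
  max_rcr_at <- function(rate) {
    ges1 <- ges1_enumerate(
      subst,
      rate_tractor = if (group == "tractor") rate else 0,
      rate_handheld = if (group == "hand_held") rate else 0,
      prot = prot, reg = reg
    )
    comb <- combined_correlated(ges1, group)
    max(comb$estimate$rcr_total,
        reentry_exposure(rate, subst, reg = reg)$rcr_total,
        bystander_exposure(rate, subst, reg = reg)$rcr_total)
  }
  hi <- 1
  it <- 0
  while (max_rcr_at(hi) < target_rcr) {
    hi <- hi * 2
    it <- it + 1
    if (it > 60) return(NA_real_)  # no constraint binds: unbounded rate
  }
  lo <- 0
  while ((hi - lo) > tol * max(hi, 1)) {
    mid <- (lo + hi) / 2
    if (max_rcr_at(mid) < target_rcr) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Run a complete screening assessment
#'
#' Resolves the application rates (fixed or maximized per technique group),
#' enumerates the selected generic exposure scenarios, appends the indirect
#' re-entry and bystander rows at each group's own rate, combines the
#' correlated spray tasks, and assembles the reportable result. The run is
#' deterministic: identical requests give identical results.
#'
#' @param request An [assessment_request()].
#' @return An object of class `owb_assessment`.
#' @export
run_full_assessment <- function(request) {
  stopifnot(inherits(request, "owb_request"))
  subst <- request$substance
  reg <- request$registry

  if (request$mode == "maximize") {
    maxres <- maximize_use_rate(subst, request$target_rcr,
                                prot = prot_for(request, "ml"), reg = reg)
    rates <- list(
      tractor = maxres$max_rate[maxres$group == "tractor"],
      hand_held = maxres$max_rate[maxres$group == "hand_held"]
    )
  } else {
    maxres <- NULL
    rates <- request$rates
  }

  out <- list(request = request, rates = rates, max_use_rates = maxres)

  if ("GES1" %in% request$ges) {
    ges1 <- ges1_enumerate(subst, rates$tractor, rates$hand_held,
                           prot = prot_for(request, "ml"), reg = reg)
    out$ges1 <- ges1
    out$combined <- list(
      tractor = combined_correlated(ges1, "tractor"),
      hand_held = combined_correlated(ges1, "hand_held")
    )
    off_rows <- list()
    for (group in c("tractor", "hand_held")) {
      rate <- if (group == "tractor") rates$tractor else rates$hand_held
      re <- reentry_exposure(rate, subst, reg = reg)
      by <- bystander_exposure(rate, subst, reg = reg)
      off_rows[[paste0(group, ".reentry")]] <- estimate_row(
        re, "Worker re-entry (indirect exposure)", "DFR/TC", "n/a", group
      )
      off_rows[[paste0(group, ".bystander")]] <- estimate_row(
        by, "Indirect exposure of bystanders", "spray drift", "n/a", group
      )
    }
    off <- do.call(rbind, off_rows)
    rownames(off) <- NULL
    off$worst_case <- FALSE
    out$offtarget <- off
    # daily amounts per technique at the group rates
    tech <- reg$techniques[reg$techniques$technique_id %in%
                             c("boom", "airblast", "handheld"), ]
    out$daily_amounts <- data.frame(
      technique = tech$technique_id,
      rate = ifelse(tech$group == "tractor", rates$tractor,
                    rates$hand_held),
      daily_amount = tech$area_per_day *
        ifelse(tech$group == "tractor", rates$tractor, rates$hand_held),
      stringsAsFactors = FALSE
    )
  }

  if ("GES2" %in% request$ges) {
    out$ges2 <- ges2_enumerate(subst, rates$tractor, request$concentration,
                               prot = prot_for(request, "ges2_loading"),
                               lev = request$lev, reg = reg)
  }

  if ("GES3" %in% request$ges) {
    sc <- consumer_scenario("spray_handheld", rates$hand_held)
    out$consumer_spray <- consumer_spray_exposure(sc, subst, reg)
  }

  if ("GES4" %in% request$ges) {
    kinds <- c("spread_hand", "spread_push", "spread_belly")
    out$consumer_solid <- lapply(kinds, function(k) {
      consumer_solid_exposure(consumer_scenario(k, rates$hand_held),
                              subst, reg)
    })
    names(out$consumer_solid) <- kinds
  }

  class(out) <- "owb_assessment"
  out
}

#' @export
print.owb_assessment <- function(x, ...) {
  cat("<owb_assessment>", x$request$substance$name, "\n")
  cat("  mode:", x$request$mode, "\n")
  cat(sprintf("  rates: tractor %.4g kg/ha, hand-held %.4g kg/ha\n",
              x$rates$tractor, x$rates$hand_held))
  if (!is.null(x$combined)) {
    for (g in names(x$combined)) {
      cat(sprintf("  combined %-9s worst technique %-8s total RCR %.3f\n",
                  g, x$combined[[g]]$worst_technique,
                  x$combined[[g]]$estimate$rcr_total))
    }
  }
  invisible(x)
}
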