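# Core domain types and the RCR / protection arithmetic shared by every
# scenario model.

#' Describe the assessed substance
#'
#' A co-formulant is characterised for screening purposes by its physical
#' state, vapour pressure, and the four external reference doses (DNELs):
#' worker and general-population, dermal and inhalation. DNELs are external
#' doses; dermal absorption is not modelled.
#'
#' @param name Substance label.
#' @param physical_state `"solid"` or `"liquid"`.
#' @param vapour_pressure Pa, non-negative.
#' @param dnel_worker_dermal mg/kg bw/day, positive.
#' @param dnel_worker_inhalation mg/m3, positive.
#' @param dnel_general_dermal mg/kg bw/day, positive.
#' @param dnel_general_inhalation mg/m3, positive.
#' @param dnel_dermal_area Optional mg/cm2/day alternative dermal reference.
#' @return An object of class `owb_substance`.
#' @examples
#' substance("example solid", "solid", 0.001, 3, 11, 1.5, 2.6)
#' @export
substance <- function(name, physical_state, vapour_pressure,
                      dnel_worker_dermal, dnel_worker_inhalation,
                      dnel_general_dermal, dnel_general_inhalation,
                      dnel_dermal_area = NULL) {
  if (!physical_state %in% c("solid", "liquid")) {
    stop("physical_state must be 'solid' or 'liquid'", call. = FALSE)
  }
  if (!is.numeric(vapour_pressure) || vapour_pressure < 0) {
    stop("vapour_pressure must be >= 0 Pa", call. = FALSE)
  }
  dnels <- c(dnel_worker_dermal = dnel_worker_dermal,
             dnel_worker_inhalation = dnel_worker_inhalation,
             dnel_general_dermal = dnel_general_dermal,
             dnel_general_inhalation = dnel_general_inhalation)
  bad <- names(dnels)[!is.finite(dnels) | dnels <= 0]
  if (length(bad)) {
    stop("DNEL(s) must be strictly positive: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  structure(
    list(name = name, physical_state = physical_state,
         vapour_pressure = vapour_pressure,
         dnel_worker_dermal = dnel_worker_dermal,
         dnel_worker_inhalation = dnel_worker_inhalation,
         dnel_general_dermal = dnel_general_dermal,
         dnel_general_inhalation = dnel_general_inhalation,
         dnel_dermal_area = dnel_dermal_area),
    class = "owb_substance"
  )
}

#' @export
print.owb_substance <- function(x, ...) {
  cat("<owb_substance>", x$name, "\n")
  cat("  state:", x$physical_state, "| vapour pressure:",
      x$vapour_pressure, "Pa\n")
  cat("  DNEL worker : dermal", x$dnel_worker_dermal,
      "mg/kg bw/day | inhalation", x$dnel_worker_inhalation, "mg/m3\n")
  cat("  DNEL general: dermal", x$dnel_general_dermal,
      "mg/kg bw/day | inhalation", x$dnel_general_inhalation, "mg/m3\n")
  invisible(x)
}

#' Protective-equipment selection
#'
#' The "No PPE" / "No RPE" columns of the screening tables correspond to the
#' all-off default.
#'
#' @param gloves,coverall Logical flags (dermal PPE).
#' @param rpe `"none"`, `"pf10"` or `"pf20"` (respiratory protection).
#' @param lev Logical, local exhaust ventilation (honoured only by tasks
#'   that support it, e.g. seed bagging).
#' @return An object of class `owb_protection`.
#' @export
protection <- function(gloves = FALSE, coverall = FALSE,
                       rpe = c("none", "pf10", "pf20"), lev = FALSE) {
  rpe <- match.arg(rpe)
  structure(list(gloves = isTRUE(gloves), coverall = isTRUE(coverall),
                 rpe = rpe, lev = isTRUE(lev)),
            class = "owb_protection")
}

protection_labels <- function(p) {
  ppe <- c(if (p$gloves) "gloves", if (p$coverall) "coverall")
  list(
    ppe = if (length(ppe)) paste(ppe, collapse = "+") else "No PPE",
    rpe = switch(p$rpe, none = "No RPE", pf10 = "RPE PF10", pf20 = "RPE PF20")
  )
}

#' Risk characterization ratios for a dermal/inhalation exposure pair
#'
#' The RCR is the exposure divided by the DNEL; the per-route ratios are
#' summed into the total. The population selects the worker or the
#' general-population DNEL set.
#'
#' @param dermal mg/kg bw/day.
#' @param inhalation mg/m3.
#' @param subst An [substance()].
#' @param population `"worker"` or `"general"`.
#' @return List with `rcr_dermal`, `rcr_inhalation`, `rcr_total`.
#' @examples
#' s <- substance("x", "solid", 0.001, 3, 11, 1.5, 2.6)
#' compute_rcr(1.982, 0.1618, s, "worker")$rcr_total  # 0.675 at 3 decimals
#' @export
compute_rcr <- function(dermal, inhalation, subst,
                        population = c("worker", "general")) {
  population <- match.arg(population)
  if (population == "worker") {
    dn_d <- subst$dnel_worker_dermal
    dn_i <- subst$dnel_worker_inhalation
  } else {
    dn_d <- subst$dnel_general_dermal
    dn_i <- subst$dnel_general_inhalation
  }
  rcr_d <- dermal / dn_d
  rcr_i <- inhalation / dn_i
  list(rcr_dermal = rcr_d, rcr_inhalation = rcr_i,
       rcr_total = rcr_d + rcr_i)
}

# Internal constructor: an exposure estimate with its RCRs and provenance.
exposure_estimate <- function(dermal, inhalation, subst, population,
                              provenance = list(), protected = FALSE) {
  stopifnot(dermal >= 0, inhalation >= 0)
  rcr <- compute_rcr(dermal, inhalation, subst, population)
  structure(
    list(dermal = dermal, inhalation = inhalation,
         rcr_dermal = rcr$rcr_dermal, rcr_inhalation = rcr$rcr_inhalation,
         rcr_total = rcr$rcr_total, population = population,
         substance = subst, protected = protected, provenance = provenance),
    class = "owb_estimate"
  )
}

#' @export
print.owb_estimate <- function(x, ...) {
  cat("<owb_estimate>", if (!is.null(x$provenance$model)) x$provenance$model,
      "\n")
  cat(sprintf("  dermal     %.4g mg/kg bw/day (RCR %.3f)\n",
              x$dermal, x$rcr_dermal))
  cat(sprintf("  inhalation %.4g mg/m3       (RCR %.3f)\n",
              x$inhalation, x$rcr_inhalation))
  cat(sprintf("  total RCR  %.3f  [%s population]\n",
              x$rcr_total, x$population))
  invisible(x)
}

#' Apply protective equipment to an unprotected estimate
#'
#' The whole-body dermal estimate is divided by the product of the active
#' dermal protection factors (gloves, coverall); the inhalation estimate is
#' divided by the RPE protection factor and, where the task supports local
#' exhaust ventilation, multiplied by one minus the LEV reduction. RCRs are
#' recomputed. Mitigation never increases an exposure.
#'
#' @param estimate An unprotected `owb_estimate`.
#' @param prot An [protection()].
#' @param reg Registry supplying the protection factors.
#' @param lev_supported Whether this task can take LEV credit.
#' @return A new `owb_estimate` flagged as protected.
#' @export
apply_protection <- function(estimate, prot, reg, lev_supported = FALSE) {
  if (isTRUE(estimate$protected)) {
    stop("protection has already been applied to this estimate",
         call. = FALSE)
  }
  pf <- reg$protection_factors
  pf_dermal <- 1
  if (prot$gloves) pf_dermal <- pf_dermal * pf$gloves_dermal_pf
  if (prot$coverall) pf_dermal <- pf_dermal * pf$coverall_dermal_pf
  pf_rpe <- switch(prot$rpe, none = 1, pf10 = 10, pf20 = 20)
  inhal <- estimate$inhalation / pf_rpe
  if (prot$lev && lev_supported) {
    inhal <- inhal * (1 - pf$lev_inhalation_reduction)
  }
  prov <- estimate$provenance
  prov$protection <- protection_labels(prot)
  exposure_estimate(estimate$dermal / pf_dermal, inhal,
                    estimate$substance, estimate$population,
                    provenance = prov, protected = TRUE)
}

#' Sum exposure estimates over correlated tasks
#'
#' Dermal and inhalation exposures (and hence the per-route and total RCRs)
#' add across tasks carried out in sequence by the same person.
#'
#' @param parts List of `owb_estimate` objects sharing a population.
#' @return A combined `owb_estimate` whose provenance lists the parts.
#' @export
combine_estimates <- function(parts) {
  if (!length(parts)) stop("no estimates to combine", call. = FALSE)
  pops <- unique(vapply(parts, function(e) e$population, character(1)))
  if (length(pops) != 1) {
    stop("cannot combine estimates across populations: ",
         paste(pops, collapse = ", "), call. = FALSE)
  }
  dermal <- sum(vapply(parts, function(e) e$dermal, numeric(1)))
  inhal <- sum(vapply(parts, function(e) e$inhalation, numeric(1)))
  exposure_estimate(
    dermal, inhal, parts[[1]]$substance, pops,
    provenance = list(
      model = "combined correlated tasks",
      parts = lapply(parts, function(e) e$provenance)
    ),
    protected = any(vapply(parts, function(e) isTRUE(e$protected),
                           logical(1)))
  )
}

# Display rounding: half away from zero, as in the published tables.
round_half_up <- function(x, digits = 3) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}
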