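# Scenario result tables: the permutation table for one contributing
# scenario, with the worst case flagged per reporting group.

# Rows must already be in canonical enumeration order (technique: boom,
# air-blast, hand-held; formulation: liquid, WP, WG; environment: outdoor,
# indoor); the first maximum within each group wins ties.
scenario_result <- function(scenario, rows, estimates) {
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  tab$worst_case <- FALSE
  for (g in unique(tab$group)) {
    idx <- which(tab$group == g)
    tab$worst_case[idx[which.max(tab$rcr_total[idx])]] <- TRUE
  }
  structure(list(scenario = scenario, table = tab, estimates = estimates),
            class = "owb_scenario_result")
}

estimate_row <- function(est, equipment, model, formulation, group,
                         environment = NA_character_) {
  lab <- if (!is.null(est$provenance$protection)) {
    est$provenance$protection
  } else {
    list(ppe = "No PPE", rpe = "No RPE")
  }
  data.frame(
    equipment = equipment, model = model, formulation = formulation,
    environment = environment, ppe = lab$ppe, rpe = lab$rpe,
    dermal = est$dermal, inhalation = est$inhalation,
    rcr_dermal = est$rcr_dermal, rcr_inhalation = est$rcr_inhalation,
    rcr_total = est$rcr_total, population = est$population, group = group,
    stringsAsFactors = FALSE
  )
}

#' Worst-case rows of a scenario result
#'
#' @param x An `owb_scenario_result`.
#' @return The flagged rows of the permutation table, one per group.
#' @export
worst_case <- function(x) {
  stopifnot(inherits(x, "owb_scenario_result"))
  x$table[x$table$worst_case, , drop = FALSE]
}

#' @export
print.owb_scenario_result <- function(x, ...) {
  cat("<owb_scenario_result>", x$scenario, "\n")
  tab <- x$table
  tab$dermal <- signif(tab$dermal, 4)
  tab$inhalation <- signif(tab$inhalation, 4)
  tab$rcr_total <- round_half_up(tab$rcr_total, 3)
  print(tab[, c("equipment", "formulation", "ppe", "rpe", "dermal",
                "inhalation", "rcr_total", "group", "worst_case")],
        row.names = FALSE)
  invisible(x)
}
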