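# Configuration parsing, result serialization, and the synthetic substance
# generator used for property-style testing.

#' Parse a run configuration into an assessment request
#'
#' The YAML/JSON document has a `substance` block, a `mode` block (either
#' `rates` or `target_rcr`), and optional `protection`, `concentration`,
#' `lev`, `ges` and `registry` entries. Unknown keys are rejected, and
#' validation errors name the offending field.
#'
#' @param path Path to a YAML (or JSON; YAML is a superset) document.
#' @return An [assessment_request()].
#' @export
parse_config <- function(path) {
  if (!file.exists(path)) {
    stop("config file not found: ", path, call. = FALSE)
  }
  doc <- yaml::read_yaml(path)
  known <- c("substance", "mode", "rates", "target_rcr", "protection",
             "concentration", "lev", "ges", "registry")
  unknown <- setdiff(names(doc), known)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  sb <- doc$substance
  if (is.null(sb)) stop("config missing 'substance' block", call. = FALSE)
  need <- c("name", "physical_state", "vapour_pressure",
            "dnel_worker_dermal", "dnel_worker_inhalation",
            "dnel_general_dermal", "dnel_general_inhalation")
  miss <- setdiff(need, names(sb))
  if (length(miss)) {
    stop("substance block missing field(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  extra <- setdiff(names(sb), c(need, "dnel_dermal_area"))
  if (length(extra)) {
    stop("unknown substance field(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  subst <- substance(sb$name, sb$physical_state, sb$vapour_pressure,
                     sb$dnel_worker_dermal, sb$dnel_worker_inhalation,
                     sb$dnel_general_dermal, sb$dnel_general_inhalation,
                     dnel_dermal_area = sb$dnel_dermal_area)

  mode <- doc$mode
  if (is.null(mode)) {
    mode <- if (!is.null(doc$target_rcr)) "maximize" else "fixed_rate"
  }
  prot <- protection()
  if (!is.null(doc$protection)) {
    pb <- doc$protection
    extra <- setdiff(names(pb), c("gloves", "coverall", "rpe", "lev"))
    if (length(extra)) {
      stop("unknown protection field(s): ", paste(extra, collapse = ", "),
           call. = FALSE)
    }
    prot <- protection(
      gloves = isTRUE(pb$gloves), coverall = isTRUE(pb$coverall),
      rpe = if (is.null(pb$rpe)) "none" else paste0("pf", pb$rpe),
      lev = isTRUE(pb$lev)
    )
  }
  reg <- if (is.null(doc$registry)) default_registry()
         else load_registry(doc$registry)
  assessment_request(
    subst, mode = mode,
    rates = doc$rates, target_rcr = doc$target_rcr, prot = prot,
    concentration = if (is.null(doc$concentration)) 0.25
                    else doc$concentration,
    lev = isTRUE(doc$lev),
    ges = if (is.null(doc$ges)) c("GES1", "GES2", "GES3", "GES4")
          else doc$ges,
    reg = reg
  )
}

#' Generate synthetic substances and scenario configurations
#'
#' Reproducible test fixtures: vapour pressures log-spread across the 0.1 Pa
#' volatility threshold (at least one substance on each side), and DNEL
#' ratios spread so that different constraints bind in rate maximization —
#' the batch always contains one substance whose general-population DNELs
#' are small enough that the bystander constraint binds.
#'
#' @param seed Integer seed.
#' @param n Number of substances, at least 1.
#' @return List of length `n`; each element has `substance` and a
#'   fixed-rate `request` built from it.
#' @export
generate_fixtures <- function(seed, n) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  set.seed(seed)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    vp <- 10^stats::runif(1, -4, 2)
    # guarantee coverage of both sides of the volatility threshold
    if (i == 1) vp <- 10^stats::runif(1, -4, -1.5)
    if (i == 2 && n >= 2) vp <- 10^stats::runif(1, 0, 2)
    dn_wd <- 10^stats::runif(1, -0.5, 1.5)
    dn_wi <- 10^stats::runif(1, 0, 2)
    ratio <- 10^stats::runif(1, 0, 1)
    dn_gd <- dn_wd / ratio
    dn_gi <- dn_wi / ratio
    if (i == 3 && n >= 3) {
      # general-population DNELs far below worker DNELs: bystander binds
      dn_gd <- dn_wd / 1000
      dn_gi <- dn_wi / 1000
    }
    st <- if (stats::runif(1) < 0.5) "solid" else "liquid"
    subst <- substance(sprintf("fixture-%02d", i), st, vp,
                       dn_wd, dn_wi, dn_gd, dn_gi)
    rates <- list(tractor = 10^stats::runif(1, -1, 0.5),
                  hand_held = 10^stats::runif(1, -1.5, 0))
    out[[i]] <- list(
      substance = subst,
      request = assessment_request(subst, mode = "fixed_rate",
                                   rates = rates)
    )
  }
  out
}

fmt_table <- function(tab, digits = 6) {
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], function(x) signif(x, digits))
  tab
}

#' Write assessment results to disk
#'
#' Emits CSV permutation tables in the documented column schema (equipment,
#' model, formulation, PPE, RPE, dermal, inhalation, RCRs, group,
#' worst-case flag), a full-precision JSON bundle, and a structured text
#' report listing models, determinants, exposures, RCRs and — in maximize
#' mode — the maximum use-rate operational condition. Output is byte-stable
#' for identical inputs.
#'
#' @param result An `owb_assessment`.
#' @param outdir Output directory, created if needed.
#' @return Character vector of the files written, invisibly.
#' @export
write_results <- function(result, outdir) {
  stopifnot(inherits(result, "owb_assessment"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  put_csv <- function(tab, name) {
    path <- file.path(outdir, name)
    utils::write.csv(fmt_table(tab), path, row.names = FALSE)
    files <<- c(files, path)
  }

  schema <- c("equipment", "model", "formulation", "ppe", "rpe", "dermal",
              "inhalation", "rcr_dermal", "rcr_inhalation", "rcr_total",
              "population", "group", "worst_case")
  empty <- stats::setNames(
    data.frame(matrix(ncol = length(schema), nrow = 0)), schema
  )

  if (!is.null(result$ges1)) {
    put_csv(result$ges1$ml$table[, c(schema)], "ges1_proc8a_ml.csv")
    app <- rbind(result$ges1$application$table[, c(schema)],
                 result$offtarget[, c(schema)])
    put_csv(app, "ges1_proc11_application.csv")
    comb <- do.call(rbind, lapply(names(result$combined), function(g) {
      cc <- result$combined[[g]]
      do.call(rbind, lapply(names(cc$per_technique), function(technique) {
        e <- cc$per_technique[[technique]]
        data.frame(group = g, technique = technique, dermal = e$dermal,
                   inhalation = e$inhalation, rcr_dermal = e$rcr_dermal,
                   rcr_inhalation = e$rcr_inhalation,
                   rcr_total = e$rcr_total,
                   worst_case = technique == cc$worst_technique,
                   stringsAsFactors = FALSE)
      }))
    }))
    put_csv(comb, "ges1_combined.csv")
    put_csv(result$daily_amounts, "daily_amounts.csv")
  } else {
    put_csv(empty, "ges1_proc8a_ml.csv")
    put_csv(empty, "ges1_proc11_application.csv")
  }
  if (!is.null(result$ges2)) {
    put_csv(result$ges2$loading$table[, c(schema)], "ges2_loading.csv")
    put_csv(result$ges2$bagging$table[, c(schema)], "ges2_bagging.csv")
    put_csv(result$ges2$dispersal$table[, c(schema)], "ges2_dispersal.csv")
  }
  if (!is.null(result$max_use_rates)) {
    put_csv(result$max_use_rates, "max_use_rates.csv")
  }

  bundle <- result_bundle(result)
  json_path <- file.path(outdir, "bundle.json")
  jsonlite::write_json(bundle, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  files <- c(files, json_path)

  report_path <- file.path(outdir, "report.txt")
  writeLines(render_report(result), report_path)
  files <- c(files, report_path)
  invisible(files)
}

est_as_list <- function(e) {
  list(dermal = e$dermal, inhalation = e$inhalation,
       rcr_dermal = e$rcr_dermal, rcr_inhalation = e$rcr_inhalation,
       rcr_total = e$rcr_total, population = e$population)
}

result_bundle <- function(result) {
  b <- list(
    substance = result$request$substance[
      c("name", "physical_state", "vapour_pressure", "dnel_worker_dermal",
        "dnel_worker_inhalation", "dnel_general_dermal",
        "dnel_general_inhalation")],
    mode = result$request$mode,
    rates = result$rates
  )
  if (!is.null(result$ges1)) {
    b$ges1 <- list(ml = result$ges1$ml$table,
                   application = result$ges1$application$table,
                   offtarget = result$offtarget)
    b$combined <- lapply(result$combined, function(cc) {
      list(worst_technique = cc$worst_technique,
           per_technique = lapply(cc$per_technique, est_as_list))
    })
    b$daily_amounts <- result$daily_amounts
  }
  if (!is.null(result$ges2)) {
    b$ges2 <- list(loading = result$ges2$loading$table,
                   bagging = result$ges2$bagging$table,
                   dispersal = result$ges2$dispersal$table,
                   correlated_pairs = result$ges2$correlated_pairs)
  }
  if (!is.null(result$consumer_spray)) {
    b$consumer_spray <- est_as_list(result$consumer_spray)
  }
  if (!is.null(result$consumer_solid)) {
    b$consumer_solid <- lapply(result$consumer_solid, est_as_list)
  }
  if (!is.null(result$max_use_rates)) {
    b$max_use_rates <- result$max_use_rates
  }
  b
}

render_report <- function(result) {
  subst <- result$request$substance
  r3 <- function(x) format(round_half_up(x, 3), nsmall = 3)
  lines <- c(
    "Screening exposure assessment report",
    "====================================",
    "",
    paste0("Substance: ", subst$name, " (", subst$physical_state,
           ", vapour pressure ", subst$vapour_pressure, " Pa)"),
    paste0("DNEL worker:  dermal ", subst$dnel_worker_dermal,
           " mg/kg bw/day, inhalation ", subst$dnel_worker_inhalation,
           " mg/m3"),
    paste0("DNEL general: dermal ", subst$dnel_general_dermal,
           " mg/kg bw/day, inhalation ", subst$dnel_general_inhalation,
           " mg/m3"),
    paste0("Mode: ", result$request$mode),
    ""
  )
  if (!is.null(result$max_use_rates)) {
    lines <- c(lines, "Maximum use rates (operational condition):")
    for (i in seq_len(nrow(result$max_use_rates))) {
      row <- result$max_use_rates[i, ]
      lines <- c(lines, sprintf(
        "  %-10s %.3f kg/ha  (binding constraint: %s)",
        row$group, row$max_rate, row$binding
      ))
    }
    lines <- c(lines, "")
  }
  if (!is.null(result$ges1)) {
    for (part in c("ml", "application")) {
      sr <- result$ges1[[part]]
      lines <- c(lines, sr$scenario, strrep("-", nchar(sr$scenario)))
      tab <- sr$table
      for (i in seq_len(nrow(tab))) {
        lines <- c(lines, sprintf(
          "  %-55s %-7s dermal %8s  inhal %8s  RCR %s%s",
          tab$equipment[i], tab$formulation[i],
          signif(tab$dermal[i], 4), signif(tab$inhalation[i], 4),
          r3(tab$rcr_total[i]),
          if (tab$worst_case[i]) "  << worst case" else ""
        ))
      }
      lines <- c(lines, "")
    }
    lines <- c(lines, "Combined correlated tasks (loading + application):")
    for (g in names(result$combined)) {
      cc <- result$combined[[g]]
      lines <- c(lines, sprintf(
        "  %-10s worst technique %-9s total RCR %s",
        g, cc$worst_technique, r3(cc$estimate$rcr_total)
      ))
    }
    lines <- c(lines, "")
  }
  lines
}
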