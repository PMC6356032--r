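# Orchestration: combined correlated tasks, use-rate maximization (closed
# form vs bisection), and the full assessment run.

test_that("combined correlated tasks pair loading and application per technique", {
  reg <- default_registry()
  s <- reference_substance()
  ges1 <- ges1_enumerate(s, RATE_TRACTOR, RATE_HANDHELD, reg = reg)

  tr <- combined_correlated(ges1, "tractor")
  expect_equal(round(tr$per_technique$boom$rcr_total, 3), 0.900)
  expect_equal(round(tr$per_technique$airblast$rcr_total, 3), 0.778)
  expect_identical(tr$worst_technique, "boom")
  # never the cross-technique sum of per-scenario maxima
  # (worst loading 0.675 on boom + worst application 0.508 on air-blast)
  expect_lt(tr$estimate$rcr_total, 0.675 + 0.508)

  hh <- combined_correlated(ges1, "hand_held")
  expect_equal(round(hh$per_technique$handheld$rcr_total, 3), 0.900)
  ml_part <- ges1$ml$estimates[["handheld.liquid"]]
  expect_equal(round(ml_part$rcr_total, 3), 0.750)
  # a single-technique group combines to that technique's own sum
  expect_equal(hh$estimate$rcr_total,
               ml_part$rcr_total +
                 ges1$application$estimates[["handheld.outdoor"]]$rcr_total)

  empty <- ges1
  empty$ml$table <- empty$ml$table[0, ]
  expect_error(combined_correlated(empty, "tractor"), "no results")
})

test_that("use-rate maximization reproduces the published rates and amounts", {
  reg <- default_registry()
  s <- reference_substance()
  mx <- maximize_use_rate(s, 0.9, reg = reg)

  tr <- mx[mx$group == "tractor", ]
  expect_equal(round(tr$max_rate, 2), 1.16)
  expect_identical(tr$binding, "combined_boom")
  hh <- mx[mx$group == "hand_held", ]
  expect_equal(round(hh$max_rate, 3), 0.768)
  expect_identical(hh$binding, "combined_handheld")

  # air-blast daily amount at the maximized tractor rate
  expect_equal(round(tr$max_rate * 8, 2), 9.25)

  # at the returned rate the binding combined RCR hits the target exactly
  ges1 <- ges1_enumerate(s, tr$max_rate, hh$max_rate, reg = reg)
  expect_equal(combined_correlated(ges1, "tractor")$estimate$rcr_total, 0.9)
  expect_equal(combined_correlated(ges1, "hand_held")$estimate$rcr_total,
               0.9)
})

test_that("maximization is homogeneous: doubling all DNELs doubles the rates", {
  reg <- default_registry()
  s <- reference_substance()
  s2 <- substance("doubled", "solid", 0.001, 6, 22, 3, 5.2)
  mx <- maximize_use_rate(s, 0.9, reg = reg)
  mx2 <- maximize_use_rate(s2, 0.9, reg = reg)
  expect_equal(mx2$max_rate, 2 * mx$max_rate)
  expect_error(maximize_use_rate(s, 1.5, reg = reg), "target RCR")
})

test_that("closed-form and bisection maximization agree on random substances", {
  reg <- default_registry()
  fixtures <- generate_fixtures(seed = 101, n = 6)
  for (fx in fixtures) {
    mx <- maximize_use_rate(fx$substance, 0.9, reg = reg)
    for (group in c("tractor", "hand_held")) {
      closed <- mx$max_rate[mx$group == group]
      bis <- maximize_use_rate_bisection(fx$substance, 0.9, reg = reg,
                                         group = group)
      expect_equal(bis, closed, tolerance = 1e-9,
                   info = paste(fx$substance$name, group))
    }
  }
})

test_that("the returned rate is maximal: 1.001x violates some constraint", {
  reg <- default_registry()
  fixtures <- generate_fixtures(seed = 202, n = 4)
  max_rcr_at <- function(subst, rate, group) {
    ges1 <- ges1_enumerate(
      subst, if (group == "tractor") rate else 0,
      if (group == "hand_held") rate else 0, reg = reg
    )
    max(combined_correlated(ges1, group)$estimate$rcr_total,
        reentry_exposure(rate, subst, reg = reg)$rcr_total,
        bystander_exposure(rate, subst, reg = reg)$rcr_total)
  }
  for (fx in fixtures) {
    mx <- maximize_use_rate(fx$substance, 0.9, reg = reg)
    for (group in c("tractor", "hand_held")) {
      rate <- mx$max_rate[mx$group == group]
      expect_equal(max_rcr_at(fx$substance, rate, group), 0.9,
                   tolerance = 1e-9)
      expect_gt(max_rcr_at(fx$substance, rate * 1.001, group), 0.9)
    }
  }
})

test_that("calibration recovers the unit exposures behind a synthetic table", {
  # parameter recovery: generate a "printed table" with the forward model,
  # then calibrate unit exposures back from it
  reg <- default_registry()
  s <- reference_substance()
  set.seed(5)
  for (technique in c("boom", "airblast", "handheld")) {
    rate <- runif(1, 0.2, 2)
    area <- reg$techniques$area_per_day[
      reg$techniques$technique_id == technique]
    for (formulation in c("liquid", "WP", "WG")) {
      est <- ml_spray_exposure(spray_scenario(technique, formulation, rate),
                               s, reg)
      q_daily <- rate * area
      task <- switch(technique, boom = "ml_boom", airblast = "ml_airblast",
                     handheld = "ml_handheld")
      expect_equal(calibrate_unit_exposure(est$dermal, q_daily, 70),
                   ue_value(reg, task, formulation, "dermal"))
      expect_equal(calibrate_unit_exposure(est$inhalation, q_daily, 10),
                   ue_value(reg, task, formulation, "inhalation"))
    }
  }
})

test_that("a full assessment run is deterministic and self-consistent", {
  reg <- default_registry()
  s <- reference_substance()
  req <- assessment_request(s, mode = "maximize", target_rcr = 0.9,
                            reg = reg)
  res <- run_full_assessment(req)
  res2 <- run_full_assessment(req)
  expect_equal(res$rates, res2$rates)
  expect_identical(res$ges1$ml$table, res2$ges1$ml$table)

  expect_equal(round(res$combined$tractor$estimate$rcr_total, 3), 0.900)
  da <- res$daily_amounts
  expect_equal(round(da$daily_amount[da$technique == "airblast"], 2), 9.25)
  expect_equal(round(da$daily_amount[da$technique == "boom"], 2), 23.11)

  # indirect rows are evaluated at each group's own rate
  off <- res$offtarget
  expect_equal(nrow(off), 4)
  re_tr <- off$dermal[off$group == "tractor" &
                        grepl("re-entry", off$equipment)]
  re_hh <- off$dermal[off$group == "hand_held" &
                        grepl("re-entry", off$equipment)]
  expect_equal(re_tr / res$rates$tractor, re_hh / res$rates$hand_held)

  zero <- run_full_assessment(assessment_request(
    s, mode = "fixed_rate", rates = list(tractor = 0, hand_held = 0),
    reg = reg
  ))
  expect_true(all(zero$ges1$ml$table$rcr_total == 0))
  expect_true(all(zero$offtarget$rcr_total == 0))

  expect_error(assessment_request(s, mode = "maximize"), "target RCR")
  expect_error(assessment_request(s, mode = "fixed_rate"), "rates")
})
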