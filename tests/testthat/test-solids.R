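# GES2: seed-treatment loading, treated-seed bagging, granule dispersal.

test_that("dispersal exposure follows the surrogate unit-exposure algebra", {
  reg <- default_registry()
  s <- reference_substance()
  rate <- 0.5
  est <- phed_exposure(
    solid_scenario("spread_tractor", application_rate = rate), s, reg
  )
  # forward arithmetic oracle: UE * Q / reference
  q_daily <- rate * 20
  expect_equal(est$dermal,
               ue_value(reg, "phed_spread_tractor", "granule", "dermal") *
                 q_daily / 70)
  expect_equal(est$inhalation,
               ue_value(reg, "phed_spread_tractor", "granule",
                        "inhalation") * q_daily / 10)

  z <- phed_exposure(solid_scenario("spread_hand", application_rate = 0),
                     s, reg)
  expect_identical(z$rcr_total, 0)
  e1 <- phed_exposure(solid_scenario("spread_belly", application_rate = 1),
                      s, reg)
  e2 <- phed_exposure(solid_scenario("spread_belly", application_rate = 2),
                      s, reg)
  expect_equal(e2$dermal, 2 * e1$dermal)

  expect_error(solid_scenario("load_spread_belly"), "unknown")
  expect_error(
    phed_exposure(solid_scenario("load_seedtreat_liquid"), s, reg),
    "not a PHED task"
  )
})

test_that("seed-treatment loading reuses the calibrated tractor-tank analogue", {
  reg <- default_registry()
  s <- reference_substance()
  expect_equal(ue_value(reg, "seedtreat_load_liquid", "liquid", "dermal"),
               0.793 * 70 / 23.12)
  expect_equal(round(ue_value(reg, "seedtreat_load_liquid", "liquid",
                              "dermal"), 3), 2.401)
  # WP ranks above liquid for inhalation (0.0700 vs 0.00061 mg/kg handled)
  expect_gt(ue_value(reg, "seedtreat_load_wp", "WP", "inhalation"),
            ue_value(reg, "seedtreat_load_liquid", "liquid", "inhalation"))

  est <- seedtreat_loading_exposure(
    solid_scenario("load_seedtreat_liquid", daily_amount = 23.12), s, reg
  )
  expect_equal(round(est$dermal, 3), 0.793)
  z <- seedtreat_loading_exposure(
    solid_scenario("load_seedtreat_wp", daily_amount = 1e-12), s, reg
  )
  expect_equal(z$dermal, ue_value(reg, "seedtreat_load_wp", "WP",
                                  "dermal") * 1e-12 / 70)
  expect_error(
    seedtreat_loading_exposure(
      solid_scenario("spread_hand", application_rate = 1), s, reg
    ),
    "liquid and WP"
  )
})

test_that("bagging is banded, concentration-monotone, and LEV-reducible", {
  reg <- default_registry()
  s <- reference_substance()
  mk <- function(conc, lev = FALSE) {
    bagging_exposure(
      solid_scenario("bag_treated_seeds", concentration = conc, lev = lev),
      s, reg
    )
  }
  on <- mk(0.5, lev = TRUE)
  off <- mk(0.5, lev = FALSE)
  expect_equal(on$inhalation / off$inhalation,
               1 - reg$protection_factors$lev_inhalation_reduction)
  expect_identical(on$dermal, off$dermal)

  concs <- c(0.005, 0.03, 0.2, 0.9)
  vals <- vapply(concs, function(cc) mk(cc)$dermal, numeric(1))
  expect_true(all(diff(vals) >= 0))

  # golden lookup: medium dustiness solid, top concentration band
  tab <- reg$bagging$table
  base <- tab[tab$state == "solid" & tab$band == "medium", ]
  expect_equal(off$dermal, base$dermal * 1)
  expect_equal(off$inhalation, base$inhalation * 1)

  # rate-independence: bagging depends on the concentration band only
  expect_error(solid_scenario("bag_treated_seeds", concentration = 1.5),
               "concentration")
  expect_error(bagging_exposure(
    solid_scenario("bag_treated_seeds", concentration = 0.5), s, reg,
    dustiness = "extreme"
  ), "band")
})

test_that("GES2 correlation never crosses the seed-treatment/dispersal split", {
  reg <- default_registry()
  s <- reference_substance()
  ges2 <- ges2_enumerate(s, rate = 1, concentration = 0.5, reg = reg)
  pairs <- ges2$correlated_pairs
  expect_length(pairs, 2)
  expect_identical(pairs[[1]], c("seed_treatment_loading", "bagging"))
  expect_identical(pairs[[2]], c("dispersal_loading", "spreading"))
  groups <- vapply(pairs, function(p) {
    any(grepl("seed_treatment", p)) && any(grepl("dispersal|spread", p))
  }, logical(1))
  expect_false(any(groups))

  # loading table keeps the two groups separate for worst-case flagging
  tab <- ges2$loading$table
  expect_setequal(unique(tab$group), c("seed_treatment", "dispersal"))
  expect_equal(sum(tab$worst_case[tab$group == "seed_treatment"]), 1)
  expect_equal(sum(tab$worst_case[tab$group == "dispersal"]), 1)
})

test_that("GES2 worst-case selection is deterministic under re-runs and zeros", {
  reg <- default_registry()
  s <- reference_substance()
  a <- ges2_enumerate(s, rate = 1, concentration = 0.5, reg = reg)
  b <- ges2_enumerate(s, rate = 1, concentration = 0.5, reg = reg)
  expect_identical(a$dispersal$table, b$dispersal$table)

  z <- ges2_enumerate(s, rate = 0, concentration = 1e-9, reg = reg)
  expect_true(all(z$dispersal$table$rcr_total == 0))
  # tie at zero: the first task in canonical order wins
  expect_identical(
    z$dispersal$table$equipment[z$dispersal$table$worst_case],
    "Tractor-mounted broadcast spreading"
  )
})
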