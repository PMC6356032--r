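# GES1 spray models: loading, application, the greenhouse vapour term, and
# the permutation enumeration with worst-case selection.

test_that("loading exposure reproduces the published boom and air-assisted rows", {
  reg <- default_registry()
  s <- reference_substance()
  e <- ml_spray_exposure(spray_scenario("boom", "WP", RATE_TRACTOR), s, reg)
  expect_equal(round(e$dermal, 3), 1.982)
  expect_equal(round(e$inhalation, 4), 0.1618)
  expect_equal(round(e$rcr_total, 3), 0.675)

  e2 <- ml_spray_exposure(spray_scenario("airblast", "liquid", RATE_TRACTOR),
                          s, reg)
  expect_equal(round(e2$dermal, 3), 0.317)

  z <- ml_spray_exposure(spray_scenario("boom", "WG", 0), s, reg)
  expect_identical(c(z$dermal, z$inhalation, z$rcr_total), c(0, 0, 0))

  expect_error(ml_spray_exposure(
    spray_scenario("spreader_tractor", "liquid", 1), s, reg
  ), "technique")
})

test_that("application exposure is formulation-independent and matches the rows", {
  reg <- default_registry()
  s <- reference_substance()
  a <- application_spray_exposure(
    spray_scenario("boom", application_rate = RATE_TRACTOR), s, reg
  )
  expect_equal(round(a$dermal, 3), 0.674)
  expect_equal(round(a$inhalation, 4), 0.0023)
  expect_equal(round(a$rcr_total, 3), 0.225)

  for (f in c("liquid", "WP", "WG")) {
    af <- application_spray_exposure(
      spray_scenario("boom", f, application_rate = RATE_TRACTOR), s, reg
    )
    expect_identical(af$dermal, a$dermal)
    expect_identical(af$inhalation, a$inhalation)
  }

  expect_error(spray_scenario("boom", application_rate = 1,
                              environment = "indoor"), "hand-held")
})

test_that("greenhouse application adds vapour only above the volatility threshold", {
  reg <- default_registry()
  nonvol <- reference_substance(vapour_pressure = 0.001)
  vol <- reference_substance(vapour_pressure = 1)

  outdoor <- application_spray_exposure(
    spray_scenario("handheld", application_rate = RATE_HANDHELD), nonvol, reg
  )
  indoor <- application_spray_exposure(
    spray_scenario("handheld", application_rate = RATE_HANDHELD,
                   environment = "indoor"), nonvol, reg
  )
  expect_equal(round(indoor$dermal, 3), 0.443)
  expect_equal(round(indoor$inhalation, 4), 0.0230)
  expect_identical(indoor$inhalation, outdoor$inhalation)

  indoor_vol <- application_spray_exposure(
    spray_scenario("handheld", application_rate = RATE_HANDHELD,
                   environment = "indoor"), vol, reg
  )
  expect_gt(indoor_vol$inhalation, outdoor$inhalation)
  expect_identical(indoor_vol$dermal, outdoor$dermal)
})

test_that("the vapour TWA matches its closed-form special cases", {
  gp <- greenhouse_params(q = 1, h = 4, tr = 8, t = 8, T = 8)
  expect_identical(crrm_twa(0, gp), 0)
  expect_equal(round(crrm_twa(1, gp), 4), 2.7345)
  # no-ventilation limit: 100 * AR * t / (2 * h * tr) as q -> 0
  for (pars in list(c(2, 3, 6), c(1, 4, 8), c(0.5, 2.5, 4))) {
    ar <- pars[1]; h <- pars[2]; t <- pars[3]
    tiny <- greenhouse_params(q = 1e-7, h = h, tr = t, t = t, T = t)
    expect_equal(crrm_twa(ar, tiny), 100 * ar * t / (2 * h * t),
                 tolerance = 1e-5)
  }
  expect_error(greenhouse_params(1, 4, tr = 4, t = 8, T = 8), "exceed")
  expect_error(crrm_twa(-1, gp), ">= 0")
})

test_that("the vapour TWA agrees with numeric integration of the air balance", {
  skip_if_not_installed("deSolve")
  # oracle: dC/dt = S - q C with S = AR * 100 / (h * tr), time-averaged
  ode_twa <- function(ar, gp) {
    src <- ar * 100 / (gp$h * gp$tr)
    deriv <- function(time, state, parms) {
      list(c(src - gp$q * state[1], state[1]))
    }
    times <- seq(0, gp$t, length.out = 2001)
    sol <- deSolve::ode(c(C = 0, cum = 0), times, deriv, NULL,
                        method = "lsoda", rtol = 1e-10, atol = 1e-12)
    unname(sol[nrow(sol), "cum"]) / gp$T
  }
  set.seed(11)
  for (k in 1:25) {
    t <- runif(1, 0.5, 10)
    gp <- greenhouse_params(q = runif(1, 0.05, 10), h = runif(1, 2, 8),
                            tr = t + runif(1, 0, 4), t = t, T = t)
    ar <- runif(1, 0.01, 5)
    expect_equal(crrm_twa(ar, gp), ode_twa(ar, gp), tolerance = 1e-6)
  }
})

test_that("the vapour TWA is monotone in ventilation and exposure time", {
  gp <- function(q, t) greenhouse_params(q = q, h = 4, tr = 10, t = t, T = 8)
  qs <- c(0.1, 0.5, 1, 2, 5, 10)
  twa_q <- vapply(qs, function(q) crrm_twa(1, gp(q, 8)), numeric(1))
  expect_true(all(diff(twa_q) < 0))
  ts <- c(1, 2, 4, 6, 8, 10)
  twa_t <- vapply(ts, function(t) crrm_twa(1, gp(1, t)), numeric(1))
  expect_true(all(diff(twa_t) > 0))
})

test_that("spray exposures scale linearly with the application rate", {
  reg <- default_registry()
  vol <- reference_substance(vapour_pressure = 5)
  set.seed(3)
  for (k in 1:10) {
    r <- runif(1, 0.01, 3)
    f <- runif(1, 1.1, 4)
    e1 <- ml_spray_exposure(spray_scenario("airblast", "WP", r), vol, reg)
    e2 <- ml_spray_exposure(spray_scenario("airblast", "WP", f * r), vol, reg)
    expect_equal(e2$dermal, f * e1$dermal)
    expect_equal(e2$rcr_total, f * e1$rcr_total)
    # including the greenhouse vapour add-on
    a1 <- application_spray_exposure(
      spray_scenario("handheld", application_rate = r,
                     environment = "indoor"), vol, reg)
    a2 <- application_spray_exposure(
      spray_scenario("handheld", application_rate = f * r,
                     environment = "indoor"), vol, reg)
    expect_equal(a2$inhalation, f * a1$inhalation)
  }
})

test_that("enumeration flags the published worst cases per group", {
  reg <- default_registry()
  s <- reference_substance()
  ges1 <- ges1_enumerate(s, RATE_TRACTOR, RATE_HANDHELD, reg = reg)

  wc_ml <- worst_case(ges1$ml)
  tractor <- wc_ml[wc_ml$group == "tractor", ]
  expect_match(tractor$equipment, "boom")
  expect_identical(tractor$formulation, "WP")
  expect_equal(round(tractor$rcr_total, 3), 0.675)
  hand <- wc_ml[wc_ml$group == "hand_held", ]
  expect_identical(hand$formulation, "liquid")
  expect_equal(round(hand$rcr_total, 3), 0.750)

  wc_app <- worst_case(ges1$application)
  tr_app <- wc_app[wc_app$group == "tractor", ]
  expect_match(tr_app$equipment, "air-assisted")
  expect_equal(round(tr_app$rcr_total, 3), 0.508)
})

test_that("worst-case tie-breaking is deterministic, first in canonical order", {
  reg <- default_registry()
  s <- reference_substance()
  ges1 <- ges1_enumerate(s, 0, 0, reg = reg)
  expect_true(all(ges1$ml$table$rcr_total == 0))
  wc <- worst_case(ges1$ml)
  # all permutations tie at zero; the first row of each group wins
  expect_identical(wc$formulation[wc$group == "tractor"], "liquid")
  expect_match(wc$equipment[wc$group == "tractor"], "boom")
  expect_identical(wc$formulation[wc$group == "hand_held"], "liquid")
})
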