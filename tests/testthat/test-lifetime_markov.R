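test_that("one-cycle probabilities follow the competing-hazard apportionment", {
  # no revision process: exit equals the life-table death probability
  lt <- flat_life_table(0.03, max_age = 120)
  spec0 <- markov_spec(60, manual_fit("exponential", c(rate = 0)),
                       lt, max_age = 120)
  p0 <- cycle_probabilities(spec0, 0)
  expect_equal(p0[["p_revision"]], 0)
  expect_equal(p0[["p_death_unrevised"]], 0.03, tolerance = 1e-12)
  expect_equal(p0[["p_death_revised"]], 0.03, tolerance = 1e-12)

  # no mortality: revision probability is the conditional survival drop
  lt0 <- flat_life_table(0, max_age = 200)
  fitw <- manual_fit("weibull", c(shape = 1.5, scale = 30))
  specw <- markov_spec(60, fitw, lt0, max_age = 200)
  p <- cycle_probabilities(specw, 4)
  expect_equal(p[["p_revision"]],
               1 - survival_prob(fitw, 5) / survival_prob(fitw, 4),
               tolerance = 1e-12)
  expect_equal(p[["p_death_unrevised"]], 0)

  # both hazards constant: closed-form apportionment 0.02 : 0.03
  ltm <- flat_life_table(1 - exp(-0.03), max_age = 200)
  spec <- markov_spec(60, manual_fit("exponential", c(rate = 0.02)),
                      ltm, max_age = 200)
  pc <- cycle_probabilities(spec, 0)
  expect_equal(pc[["p_revision"]], 0.4 * (1 - exp(-0.05)), tolerance = 1e-12)
  expect_equal(pc[["p_death_unrevised"]], 0.6 * (1 - exp(-0.05)),
               tolerance = 1e-12)
})

test_that("state occupancy is conserved and monotone along the trace", {
  co <- generate_cohort(cohort_config(seed = 8), fixture_lt)
  fit <- fit_parametric("exponential", as_surv_data(co))
  tr <- run_markov(markov_spec(55, fit, fixture_lt))
  expect_true(all(abs(tr$unrevised + tr$revised + tr$dead - 1) < 1e-12))
  expect_true(all(diff(tr$dead) >= -1e-15))
  expect_true(all(diff(tr$unrevised) <= 1e-15))
  expect_true(all(tr$newly_revised >= 0))
  expect_equal(tr$attained_age, 55 + tr$cycle)
})

test_that("without mortality the unrevised curve is the fitted survival", {
  lt0 <- flat_life_table(0, max_age = 200)
  lam <- 0.03
  tr <- run_markov(markov_spec(60, manual_fit("exponential", c(rate = lam)),
                               lt0, max_age = 200))
  expect_equal(tr$unrevised, exp(-lam * tr$cycle), tolerance = 1e-12)
})

test_that("flat competing hazards give lifetime risk lam_r/(lam_r + lam_m)", {
  lam_r <- 0.01; lam_m <- 0.04
  lt <- flat_life_table(1 - exp(-lam_m), max_age = 700)
  spec <- markov_spec(0, manual_fit("exponential", c(rate = lam_r)),
                      lt, max_age = 700)
  est <- lifetime_risk(run_markov(spec))
  expect_equal(est$risk, lam_r / (lam_r + lam_m), tolerance = 1e-8)
})

test_that("a cohort entering at 85 is mostly dead within about seven cycles", {
  fit <- manual_fit("exponential", c(rate = 0.0057))
  tr <- run_markov(markov_spec(85, fit, fixture_lt))
  expect_gt(tr$dead[tr$cycle == 7], 0.5)
})

test_that("lifetime risk declines with entry age and rises with the hazard", {
  fit <- manual_fit("exponential", c(rate = 0.0057))
  risks <- vapply(c(55, 60, 65, 70, 75, 80, 85), function(a)
    lifetime_risk(run_markov(markov_spec(a, fit, fixture_lt)))$risk, numeric(1))
  expect_true(all(diff(risks) < 0))

  for (a in c(55, 65, 75, 85)) {
    base <- lifetime_risk(run_markov(markov_spec(a, fit, fixture_lt)))$risk
    doubled <- lifetime_risk(run_markov(apply_scenario(
      markov_spec(a, fit, fixture_lt),
      scenario_config(global_hazard_multiplier = 2))))$risk
    expect_gt(doubled, base)
  }
})

test_that("scenarios modify hazards only where they claim to", {
  fit <- manual_fit("exponential", c(rate = 0.0057))
  spec <- markov_spec(65, fit, fixture_lt)
  base <- lifetime_risk(run_markov(spec))$risk

  identity <- scenario_config(age_threshold = NULL, global_hazard_multiplier = 1)
  expect_equal(lifetime_risk(run_markov(apply_scenario(spec, identity)))$risk,
               base, tolerance = 1e-15)

  halved90 <- scenario_config(age_threshold = 90,
                              hazard_multiplier_above_threshold = 0.5)
  r90 <- lifetime_risk(run_markov(apply_scenario(spec, halved90)))$risk
  expect_lt(r90, base)
  # hazard below the threshold is untouched: traces agree up to age 90
  tr_a <- run_markov(spec); tr_b <- run_markov(apply_scenario(spec, halved90))
  below <- tr_a$attained_age < 90
  expect_equal(tr_b$unrevised[below], tr_a$unrevised[below], tolerance = 1e-15)

  zeroed <- scenario_config(age_threshold = 0,
                            hazard_multiplier_above_threshold = 0)
  expect_equal(lifetime_risk(run_markov(apply_scenario(spec, zeroed)))$risk, 0)

  expect_error(scenario_config(global_hazard_multiplier = -1), "> 0")
})

test_that("predicted incidence matches hand arithmetic and recovers the hazard", {
  toy <- structure(data.frame(
    cycle = 0:3, attained_age = 60:63,
    unrevised = c(1, 0.95, 0.90, 0.85),
    revised = c(0, 0.01, 0.02, 0.03),
    dead = c(0, 0.04, 0.08, 0.12),
    newly_revised = c(0.01, 0.01, 0.01, 0)),
    entry_age = 60, family = "exponential",
    class = c("state_trace", "data.frame"))
  expect_equal(predicted_incidence_rate(toy, horizon = 3),
               100 * 0.03 / (0.975 + 0.925 + 0.875), tolerance = 1e-12)
  expect_error(predicted_incidence_rate(toy, horizon = 10), "horizon")

  # with no mortality the 10-year rate recovers the generating hazard < 1%
  lt0 <- flat_life_table(0, max_age = 200)
  tr <- run_markov(markov_spec(60, manual_fit("exponential", c(rate = 0.0057)),
                               lt0, max_age = 200))
  expect_equal(predicted_incidence_rate(tr, 10), 0.57, tolerance = 0.01)

  tr0 <- run_markov(markov_spec(60, manual_fit("exponential", c(rate = 0)),
                                lt0, max_age = 200))
  expect_equal(predicted_incidence_rate(tr0, 10), 0)
})

test_that("observed incidence counts events over truncated person-time", {
  expect_equal(observed_incidence_rate(toy_cohort(10, 1)), 10)
  expect_equal(observed_incidence_rate(toy_cohort(c(5, 15), c(1, 0))),
               100 * 1 / 15, tolerance = 1e-12)
  expect_error(observed_incidence_rate(toy_cohort(numeric(0), integer(0))),
               "empty")
})

test_that("model-predicted incidence tracks the observed cohort rate", {
  co <- generate_cohort(cohort_config(seed = 55), fixture_lt)
  fit <- fit_parametric("exponential", as_surv_data(co))
  # predict for the cohort's mean entry age, as the validation plot does
  tr <- run_markov(markov_spec(round(mean(co$age_at_surgery)), fit, fixture_lt))
  pred <- predicted_incidence_rate(tr, 10)
  obs <- observed_incidence_rate(co, 10)
  expect_equal(pred, obs, tolerance = 0.15)
})

test_that("the microsimulation agrees with the deterministic trace in expectation", {
  fit <- manual_fit("exponential", c(rate = 0.0057))
  spec <- markov_spec(65, fit, fixture_lt)
  det <- run_markov(spec)
  n <- 20000L
  mic <- run_microsim(spec, n = n, seed = 99)
  at10 <- function(df, col) df[df$cycle == 10, col]
  for (col in c("unrevised", "revised", "dead")) {
    p <- at10(det, col)
    se <- sqrt(max(p * (1 - p), 1e-12) / n)
    expect_lt(abs(at10(mic, col) / n - p), 4 * se + 1e-6, label = col)
  }
})

test_that("trace CSV export round-trips the occupancy columns", {
  fit <- manual_fit("exponential", c(rate = 0.0057))
  tr <- run_markov(markov_spec(80, fit, fixture_lt))
  path <- withr::local_tempfile(fileext = ".csv")
  write_state_trace(tr, path)
  back <- utils::read.csv(path)
  expect_equal(names(back),
               c("cycle", "attained_age", "unrevised", "revised", "dead",
                 "newly_revised"))
  expect_equal(back$unrevised, tr$unrevised, tolerance = 1e-12)
})
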