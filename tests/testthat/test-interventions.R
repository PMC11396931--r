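test_that("coverage ramps linearly from baseline to target, then stops", {
  mkt <- default_interventions()[["marketing_restrictions"]]
  expect_equal(coverage_path(mkt, 2020), 0)
  expect_equal(coverage_path(mkt, 2025), 0)
  expect_equal(coverage_path(mkt, 2035), 0.8 * 10 / 19, tolerance = 1e-12)
  expect_equal(coverage_path(mkt, 2044), 0.8)
  expect_equal(coverage_path(mkt, 2045), 0)

  fopl <- default_interventions()[["fopl"]]
  expect_equal(coverage_path(fopl, 2024), 0.05)
  expect_equal(coverage_path(fopl, 2044), 1.00)  # full mandatory coverage
})

test_that("applying a prevalence effect moves mass into normal weight", {
  st <- toy_states_single(age0 = 85, pop = 100,
                          prev = c(normal = 0.6, overweight = 0.25,
                                   obese = 0.15))
  # coverage 0.8 x effect 0.1 on the overweight+obese mass
  out <- apply_effect(st, 0.8 * 0.1)
  expect_equal(out$prev_overweight[1], 0.230, tolerance = 1e-12)
  expect_equal(out$prev_obese[1], 0.138, tolerance = 1e-12)
  expect_equal(out$prev_normal[1], 0.632, tolerance = 1e-12)
  expect_equal(out$prev_normal + out$prev_overweight + out$prev_obese,
               rep(1, nrow(out)), tolerance = 1e-12)
  # zero coverage or zero effect leaves the state untouched
  expect_equal(apply_effect(st, 0)$prev_obese, st$prev_obese)
  expect_error(apply_effect(st, 1.2), class = "oaoinvest_spec_error")
})

test_that("combination rules match direct evaluation and their ordering", {
  expect_equal(combine_reductions(0.3), 0.3)
  expect_equal(combine_reductions(c(0.1, 0.2)), 0.28, tolerance = 1e-12)
  expect_equal(combine_reductions(c(0.1, 0.2), "additive_capped"), 0.3)
  set.seed(5)
  for (i in 1:50) {
    r <- runif(3)
    expect_equal(combine_reductions(r), 1 - (1 - r[1]) * (1 - r[2]) *
                   (1 - r[3]), tolerance = 1e-12)
    expect_equal(combine_reductions(r, "additive_capped"),
                 min(sum(r), 1), tolerance = 1e-12)
    expect_gte(combine_reductions(r, "additive_capped"),
               combine_reductions(r))
  }
  expect_error(combine_reductions(numeric(0)),
               class = "oaoinvest_spec_error")
  expect_error(combine_reductions(c(0.2, 1.4)),
               class = "oaoinvest_spec_error")
})

test_that("per-person cost streams are covered persons times unit cost", {
  # 1000 eligible persons at every age, coverage ramping 0 -> 1 over
  # 2025-2044, unit cost 2: mid-window coverage 0.5 costs 1000/yr
  years <- 2025 + 0:60
  st <- make_toy_states(
    tibble::tibble(age0 = 10, sex = "male", year = years,
                   age = 10 + years - 2025, population = 1000,
                   mean_bmi = 24, bmi_sd = 3, prev_normal = 0.5,
                   prev_overweight = 0.3, prev_obese = 0.2),
    2025, 90
  )
  sp <- intervention_spec("x", c(0, 90), "all", 0, 1, effect = 0.1,
                          unit_cost = 2, window = c(2025, 2044))
  cs <- cost_stream(sp, st)
  expect_equal(cs$cost[cs$year == 2034], 1000 * (9 / 19) * 2 * 1,
               tolerance = 1e-12)
  expect_equal(cs$cost[cs$year == 2044], 1000 * 1 * 2, tolerance = 1e-12)
  expect_true(all(cs$cost[cs$year > 2044] == 0))

  # affected-only targeting scales by overweight+obese prevalence
  sp_aff <- intervention_spec("y", c(0, 90), "affected", 0, 1, effect = 0.1,
                              unit_cost = 2, window = c(2025, 2044))
  cs_aff <- cost_stream(sp_aff, st)
  expect_equal(cs_aff$cost, cs$cost * 0.5, tolerance = 1e-12)

  # zero incremental coverage means a zero stream
  sp0 <- intervention_spec("z", c(0, 90), "all", 0.4, 0.4, effect = 0.1,
                           unit_cost = 2, window = c(2025, 2044))
  expect_true(all(cost_stream(sp0, st)$cost == 0))
})

test_that("programme costs are flat within the window and additive", {
  setup <- small_setup()
  ints <- default_interventions()
  mkt <- cost_stream(ints$marketing_restrictions, setup$states)
  expect_true(all(mkt$cost[mkt$year %in% 2025:2044] == 225000))
  expect_true(all(mkt$cost[mkt$year > 2044] == 0))
  # package stream is exactly the sum of member streams
  members <- ints[c("marketing_restrictions", "fopl", "school_based")]
  total <- cost_stream_total(members, setup$states)
  by_hand <- Reduce(`+`, lapply(members, function(s) {
    cost_stream(s, setup$states)$cost
  }))
  expect_identical(total$cost, by_hand)
})

test_that("reductions ratchet through eligibility and persist via tracking", {
  sp <- intervention_spec("m", c(2, 18), "all", 0, 0.8, effect = 0.1,
                          unit_cost = 0, cost_mode = "program",
                          window = c(2025, 2044))
  years <- 2025 + 0:70
  st <- make_toy_states(
    tibble::tibble(age0 = 10, sex = "male", year = years,
                   age = 10 + years - 2025, population = 100,
                   mean_bmi = 24, bmi_sd = 3, prev_normal = 0.5,
                   prev_overweight = 0.3, prev_obese = 0.2),
    2025, 90
  )
  red <- scenario_reductions(list(sp), st, tracking = 0.6)
  red <- red[order(red$year), ]
  # eligible ages 10..18 (years 2025..2033): active ramp x effect
  active <- pmax(coverage_path(sp, 2025:2033), 0) * 0.1
  expect_equal(red$reduction[1:9], pmax(active, 0.6 * cummax(active)),
               tolerance = 1e-12)
  # after ageing out at 19: tracked at 0.6 x the best achieved, for life
  peak <- max(active)
  expect_equal(red$reduction[10:nrow(red)],
               rep(0.6 * peak, nrow(red) - 9), tolerance = 1e-12)
})

test_that("higher coverage or effect never raises scenario OAO prevalence", {
  st <- small_setup()$states
  oao_total <- function(target_cov, effect) {
    sp <- intervention_spec("m", c(2, 18), "all", 0, target_cov,
                            effect = effect, unit_cost = 0,
                            cost_mode = "program", window = c(2025, 2044))
    red <- scenario_reductions(list(sp), st)
    out <- apply_effect(st, red)
    sum(out$population * (out$prev_overweight + out$prev_obese))
  }
  by_cov <- vapply(c(0.2, 0.5, 0.8), oao_total, numeric(1), effect = 0.1)
  expect_true(all(diff(by_cov) <= 1e-9))
  by_eff <- vapply(c(0.05, 0.1, 0.2), function(e) oao_total(0.8, e),
                   numeric(1))
  expect_true(all(diff(by_eff) <= 1e-9))
})

test_that("specification invariants are enforced", {
  expect_error(intervention_spec("x", c(5, 2), "all", 0, 0.5, 0.1, 1),
               class = "oaoinvest_spec_error")
  expect_error(intervention_spec("x", c(2, 5), "all", 0.6, 0.5, 0.1, 1),
               class = "oaoinvest_spec_error")
  expect_error(intervention_spec("x", c(2, 5), "all", 0, 1.5, 0.1, 1),
               class = "oaoinvest_spec_error")
  expect_error(intervention_spec("x", c(2, 5), "all", 0, 0.5, -0.1, 1),
               class = "oaoinvest_spec_error")
  expect_error(package_spec("p", character(0)),
               class = "oaoinvest_spec_error")
  expect_error(package_spec("p", c("a", "a")),
               class = "oaoinvest_spec_error")
})

test_that("the packaged YAML roster matches the built-in defaults", {
  path <- system.file("extdata", "interventions.yaml",
                      package = "oaoinvest")
  cfg <- read_intervention_config(path)
  defaults <- default_interventions()
  expect_setequal(names(cfg$interventions), names(defaults))
  for (nm in names(defaults)) {
    expect_equal(cfg$interventions[[nm]], defaults[[nm]], label = nm)
  }
  expect_setequal(names(cfg$packages), names(default_packages()))
  expect_equal(cfg$packages$package_1$members,
               c("marketing_restrictions", "fopl"))
})
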