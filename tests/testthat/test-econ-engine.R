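toy_params <- function(r = 0.03, M = 1.6, gdp = 100, xr = 7.1,
                       wage = 1000, penalty = 0.05, ap = 0.03) {
  econ_params(
    discount_rate = r, gdp_multiplier = M, gdp_per_capita = gdp,
    exchange_rate = xr, wage = wage, wage_penalty = penalty,
    absenteeism_loss = ap,
    employment = tibble::tibble(age = as.numeric(0:89),
                                rate = ifelse(0:89 >= 20 & 0:89 < 60,
                                              0.8, 0)),
    healthcare_unit_cost = tibble::tibble(
      life_stage = rep(c("child", "adult"), each = 2),
      category = rep(c("overweight", "obese"), 2),
      excess_cost = c(10, 30, 20, 50)
    ),
    index_year = 2025
  )
}

test_that("discounting matches its closed forms", {
  p <- toy_params()
  expect_equal(discount(100, 2025, p), 100)
  expect_equal(discount(103, 2026, p), 100, tolerance = 1e-12)
  # 30-year unit annuity
  years <- 2025:2054
  expect_equal(sum(discount(rep(1, 30), years, p)),
               (1 - 1.03^-30) / 0.03 * 1.03, tolerance = 1e-10)
  # the model convention pays the first unit in the index year (t = 0), so
  # compare against the annuity-due form above and the ordinary annuity via
  # a one-year shift
  expect_equal(sum(discount(rep(1, 30), years + 1, p)),
               (1 - 1.03^-30) / 0.03, tolerance = 1e-10)
  expect_true(all(discount(rep(5, 30), years, p)[-1] < 5))
  expect_error(discount(1, 2024, p), class = "oaoinvest_econ_error")
})

test_that("mortality value is YLL x GDP per capita x multiplier", {
  p <- toy_params()
  expect_equal(mortality_value(0, p), 0)
  expect_equal(mortality_value(1, p), 160)
  expect_equal(mortality_value(c(2, 3), p), c(320, 480))
  expect_error(mortality_value(-1, p), class = "oaoinvest_econ_error")
})

test_that("healthcare costs equal the hand sum on a toy cohort", {
  # two ages (one child, one adult), explicit prevalences
  years <- 2025:2026
  st <- make_toy_states(dplyr::bind_rows(
    tibble::tibble(age0 = 10, sex = "male", year = years,
                   age = c(10, 11), population = 100, mean_bmi = 20,
                   bmi_sd = 2, prev_normal = 0.6, prev_overweight = 0.3,
                   prev_obese = 0.1),
    tibble::tibble(age0 = 19, sex = "female", year = years,
                   age = c(19, 20), population = 200, mean_bmi = 23,
                   bmi_sd = 2.5, prev_normal = 0.5, prev_overweight = 0.3,
                   prev_obese = 0.2)
  ), 2025, 21)
  d <- toy_disease("d", 1.2, 1.5, mortality = 0, yld = 0, max_age = 21)
  led <- run_cohort(st, list(d), toy_mortality(0, max_age = 21))
  p <- toy_params()
  hc <- healthcare_costs(st, led, p)
  # year 2025: child 100*(0.3*10+0.1*30) = 600; child 200*(.3*10+.2*30)=1800
  expect_equal(hc$healthcare_child[hc$year == 2025], 600 + 1800)
  expect_equal(hc$healthcare_adult[hc$year == 2025], 0)
  # year 2026 (no mortality): ages 11 (child) and 20 (adult)
  expect_equal(hc$healthcare_child[hc$year == 2026], 600)
  expect_equal(hc$healthcare_adult[hc$year == 2026],
               200 * (0.3 * 20 + 0.2 * 50))
  # zero prevalence, zero attributable cost
  st0 <- st
  st0$prev_overweight <- 0; st0$prev_obese <- 0; st0$prev_normal <- 1
  led0 <- run_cohort(st0, list(d), toy_mortality(0, max_age = 21))
  hc0 <- healthcare_costs(st0, led0, p)
  expect_true(all(hc0$healthcare_child == 0 & hc0$healthcare_adult == 0))
})

test_that("wage and productivity losses match direct enumeration", {
  years <- 2025:2026
  st <- make_toy_states(
    tibble::tibble(age0 = 24, sex = "male", year = years,
                   age = c(24, 25), population = 1000, mean_bmi = 25,
                   bmi_sd = 3, prev_normal = 0.5, prev_overweight = 0.3,
                   prev_obese = 0.2),
    2025, 27
  )
  d <- toy_disease("d", 1.2, 1.5, mortality = 0, max_age = 27)
  led <- run_cohort(st, list(d), toy_mortality(0, max_age = 27))
  p <- toy_params()
  wp <- wage_and_productivity_losses(st, led, p)
  workers <- 1000 * 0.5 * 0.8           # OAO prevalence x employment
  expect_equal(wp$wage_loss, rep(workers * 1000 * 0.05, 2),
               tolerance = 1e-12)
  expect_equal(wp$productivity_loss, rep(workers * 1000 * 0.03, 2),
               tolerance = 1e-12)
  # both channels vanish when the penalties are zero
  p0 <- toy_params(penalty = 0, ap = 0)
  wp0 <- wage_and_productivity_losses(st, led, p0)
  expect_true(all(wp0$wage_loss == 0 & wp0$productivity_loss == 0))
})

test_that("econ ledger streams have discounted twins that never exceed them", {
  setup <- small_setup()
  led <- run_cohort(setup$states, setup$diseases, setup$bundle$mortality)
  params <- econ_params(setup$bundle)
  el <- build_econ_ledger(setup$states, led, params)
  for (nm in c("healthcare_child", "healthcare_adult", "wage_loss",
               "productivity_loss", "mortality_value")) {
    expect_true(all(el[[paste0(nm, "_disc")]] <= el[[nm]] + 1e-9),
                label = nm)
  }
})

test_that("roi is net benefit over cost with its degenerate cases", {
  expect_equal(roi(100, 100), 0)
  expect_equal(roi(250, 100), 1.5)
  expect_lt(roi(0, 100), 0)     # no benefit: ROI = -1
  expect_equal(roi(0, 100), -1)
  expect_error(roi(100, 0), class = "oaoinvest_econ_error")
  expect_error(roi(100, -5), class = "oaoinvest_econ_error")
})

test_that("roi grows with horizon when costs end before benefits", {
  p <- toy_params()
  years <- 2025:2114
  benefits <- tibble::tibble(
    year = years,
    total = ifelse(years >= 2026, (years - 2025) * 10, 0)
  )
  costs <- tibble::tibble(year = years,
                          cost = ifelse(years <= 2044, 100, 0))
  tbl <- roi_by_horizon(benefits, costs, p, horizons = c(10, 30, 50, Inf))
  expect_true(all(diff(tbl$roi) >= 0))
  # null benefits give ROI exactly -1 at every horizon
  null_tbl <- roi_by_horizon(dplyr::mutate(benefits, total = 0), costs, p)
  expect_true(all(null_tbl$roi == -1))
})

test_that("roi falls with the discount rate and is affine in the multiplier", {
  years <- 2025:2114
  benefits <- tibble::tibble(
    year = years, total = ifelse(years >= 2040, 500, 0)
  )
  costs <- tibble::tibble(year = years,
                          cost = ifelse(years <= 2044, 100, 0))
  rois <- vapply(c(0, 0.03, 0.06, 0.1), function(r) {
    roi_by_horizon(benefits, costs, toy_params(r = r),
                   horizons = Inf)$roi
  }, numeric(1))
  expect_true(all(diff(rois) < 0))

  # benefits that are pure mortality value scale linearly in the multiplier,
  # so ROI + 1 is proportional to M
  p1 <- toy_params(M = 1)
  yll <- rep(2, length(years))
  roi_for <- function(M) {
    p <- toy_params(M = M)
    b <- tibble::tibble(year = years, total = mortality_value(yll, p))
    roi_by_horizon(b, costs, p, horizons = Inf)$roi
  }
  r1 <- roi_for(1); r2 <- roi_for(2); r4 <- roi_for(4)
  expect_equal((r2 + 1) / (r1 + 1), 2, tolerance = 1e-9)
  expect_equal((r4 + 1) / (r1 + 1), 4, tolerance = 1e-9)
})

test_that("econ parameter validation catches bad inputs", {
  expect_error(toy_params(r = -0.01), class = "oaoinvest_econ_error")
  expect_error(toy_params(M = 0), class = "oaoinvest_econ_error")
  expect_error(toy_params(penalty = 1.2), class = "oaoinvest_econ_error")
  expect_error(econ_params(discount_rate = 0.03),
               class = "oaoinvest_econ_error")  # missing tables
})
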