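test_that("pif is zero for unchanged exposure or unit relative risks", {
  p <- c(normal = 0.5, overweight = 0.3, obese = 0.2)
  rr <- c(normal = 1, overweight = 1.5, obese = 2.5)
  expect_equal(pif(p, p, rr), 0)
  q <- c(normal = 0.7, overweight = 0.2, obese = 0.1)
  expect_equal(pif(p, q, c(normal = 1, overweight = 1, obese = 1)), 0)
  expect_error(pif(p, q[1:2], rr), class = "oaoinvest_pif_error")
})

test_that("pif equals the weighted-sum oracle, including worsening", {
  p <- c(normal = 0.5, overweight = 0.3, obese = 0.2)
  q <- c(normal = 0.6, overweight = 0.25, obese = 0.15)
  rr <- c(normal = 1, overweight = 1.5, obese = 2.5)
  expect_equal(pif(p, q, rr), pif_oracle(p, q, rr), tolerance = 1e-12)
  # swapping the roles makes the scenario worse: PIF < 0
  expect_lt(pif(q, p, rr), 0)

  set.seed(77)
  for (i in 1:200) {
    pb <- as.numeric(stats::rexp(3)); pb <- pb / sum(pb)
    ps <- as.numeric(stats::rexp(3)); ps <- ps / sum(ps)
    names(pb) <- names(ps) <- c("normal", "overweight", "obese")
    r <- c(normal = 1, overweight = runif(1, 1, 3))
    r["obese"] <- runif(1, r[["overweight"]], 4)
    expect_equal(pif(pb, ps, r), pif_oracle(pb, ps, r), tolerance = 1e-12)
  }
})

test_that("a 1-person toy cohort matches the enumerated death years", {
  # age 88, one disease with mortality 0.5/yr, no background, horizon 90:
  # die at 88 (p = 1/2, 2 years lost) or at 89 (p = 1/4, 1 year lost)
  st <- toy_states_single(age0 = 88, pop = 1)
  d <- toy_disease("d", 1.5, 2.5, mortality = 0.5)
  led <- run_cohort(st, list(d), toy_mortality(0.5))
  expect_equal(sum(led$yll), 0.5 * 2 + 0.25 * 1, tolerance = 1e-12)
  expect_equal(sum(led$deaths), 0.75, tolerance = 1e-12)
})

test_that("the engine matches exhaustive enumeration on toy cohorts", {
  set.seed(99)
  max_age <- 90
  for (rep in 1:4) {
    ages0 <- sort(sample(80:88, sample(1:3, 1)))
    q1 <- runif(1, 0.05, 0.2); q2 <- runif(1, 0.05, 0.2)
    all_cause_rate <- q1 + q2 + runif(1, 0.05, 0.3)
    d1 <- toy_disease("d1", 1.4, 2.2, mortality = q1, yld = 0.02)
    d2 <- toy_disease("d2", 1.2, 3.0, mortality = q2, yld = 0.05)

    rows <- lapply(ages0, function(a0) {
      years <- 2025 + 0:(max_age - 1 - a0)
      tibble::tibble(age0 = a0, sex = "male", year = years,
                     age = a0 + years - 2025, population = 100,
                     mean_bmi = 24, bmi_sd = 3,
                     prev_normal = 0.5, prev_overweight = 0.3,
                     prev_obese = 0.2)
    })
    st <- make_toy_states(dplyr::bind_rows(rows), 2025, max_age)

    # random PIF streams per stratum/year/disease
    pifs <- dplyr::bind_rows(lapply(ages0, function(a0) {
      years <- 2025 + 0:(max_age - 1 - a0)
      tidyr::expand_grid(age0 = a0, sex = "male", year = years,
                         disease = c("d1", "d2")) |>
        dplyr::mutate(pif = runif(dplyr::n(), -0.2, 0.9))
    }))

    led <- run_cohort(st, list(d1, d2), toy_mortality(all_cause_rate),
                      pifs = pifs, scenario = "toy")
    pt <- attr(led, "person_time")

    expected <- lapply(ages0, function(a0) {
      ny <- max_age - a0
      pm <- matrix(0, ny, 2)
      for (j in 1:2) {
        sub <- pifs[pifs$age0 == a0 & pifs$disease == c("d1", "d2")[j], ]
        pm[, j] <- sub$pif[order(sub$year)]
      }
      q_dis <- cbind(rep(q1, max_age), rep(q2, max_age))
      yld_dis <- cbind(rep(0.02, max_age), rep(0.05, max_age))
      cohort_oracle(100, a0, max_age, rep(all_cause_rate, max_age),
                    q_dis, yld_dis, pm)
    })
    exp_deaths <- sum(vapply(expected, function(e) sum(e$deaths),
                             numeric(1)))
    exp_yll <- sum(vapply(expected, function(e) sum(e$yll), numeric(1)))
    exp_yld <- sum(vapply(expected, function(e) sum(e$yld), numeric(1)))
    expect_equal(sum(led$deaths), exp_deaths, tolerance = 1e-9)
    expect_equal(sum(led$yll), exp_yll, tolerance = 1e-9)
    expect_equal(sum(led$yld), exp_yld, tolerance = 1e-9)

    # conservation: survivors next year = survivors - deaths, per stratum
    for (a0 in ages0) {
      sub <- pt[pt$age0 == a0, ]
      sub <- sub[order(sub$year), ]
      oracle <- expected[[match(a0, ages0)]]
      expect_equal(sub$alive, oracle$alive, tolerance = 1e-9)
      n <- nrow(sub)
      if (n > 1) {
        expect_equal(sub$alive[-1], sub$alive[-n] - oracle$deaths[-n],
                     tolerance = 1e-9)
      }
    }
  }
})

test_that("ledger cells satisfy DALY = YLL + YLD and stay in horizon", {
  setup <- small_setup()
  led <- run_cohort(setup$states, setup$diseases, setup$bundle$mortality)
  expect_equal(led$daly, led$yll + led$yld, tolerance = 1e-9)
  expect_true(all(led$deaths >= 0 & led$yll >= 0 & led$yld >= 0))
  expect_true(all(led$year <= setup$bundle$config$index_year +
                    setup$bundle$config$max_age - 1))
  # sex-specific totals add to the all-person total
  tot <- sum(led$daly)
  by_sex <- tapply(led$daly, led$sex, sum)
  expect_equal(sum(by_sex), tot, tolerance = 1e-9)
})

test_that("raising any PIF never increases deaths, YLL, YLD or DALYs", {
  st <- toy_states_single(age0 = 85, pop = 1000,
                          prev = c(normal = 0.5, overweight = 0.3,
                                   obese = 0.2))
  d <- toy_disease("d", 1.5, 2.5, mortality = 0.1, yld = 0.03)
  mk_pifs <- function(v) {
    tibble::tibble(age0 = 85, sex = "male", year = 2025:2029,
                   disease = "d", pif = v)
  }
  vals <- seq(0, 1, by = 0.2)
  leds <- lapply(vals, function(v) {
    run_cohort(st, list(d), toy_mortality(0.2), pifs = mk_pifs(v))
  })
  for (col in c("deaths", "yll", "yld", "daly")) {
    totals <- vapply(leds, function(l) sum(l[[col]]), numeric(1))
    expect_true(all(diff(totals) <= 1e-12), label = col)
  }
  expect_error(run_cohort(st, list(d), toy_mortality(0.2),
                          pifs = mk_pifs(1.5)),
               class = "oaoinvest_engine_error")
})

test_that("compute_pifs applies the one-year implementation lag", {
  st <- toy_states_single(age0 = 85, pop = 100,
                          prev = c(normal = 0.5, overweight = 0.3,
                                   obese = 0.2))
  scen <- apply_effect(st, 0.5)
  d <- toy_disease("d", 1.5, 2.5, mortality = 0.1)
  pifs <- compute_pifs(st, scen, list(d), lag = 1)
  pifs <- pifs[order(pifs$year), ]
  expect_equal(pifs$pif[1], 0)  # nothing before the lag
  raw <- pif(c(normal = 0.5, overweight = 0.3, obese = 0.2),
             c(normal = 0.75, overweight = 0.15, obese = 0.1),
             c(normal = 1, overweight = 1.5, obese = 2.5))
  expect_equal(pifs$pif[-1], rep(raw, nrow(pifs) - 1), tolerance = 1e-12)
  # without lag the PIF applies immediately
  pifs0 <- compute_pifs(st, scen, list(d), lag = 0)
  expect_equal(pifs0$pif, rep(raw, nrow(pifs0)), tolerance = 1e-12)
})

test_that("dalys_averted is the elementwise difference with its identity", {
  st <- toy_states_single(age0 = 85, pop = 1000,
                          prev = c(normal = 0.5, overweight = 0.3,
                                   obese = 0.2))
  d <- toy_disease("d", 1.5, 2.5, mortality = 0.1, yld = 0.03)
  base <- run_cohort(st, list(d), toy_mortality(0.2))
  expect_true(all(dalys_averted(base, base)$daly == 0))

  pifs <- tibble::tibble(age0 = 85, sex = "male", year = 2025:2029,
                         disease = "d", pif = 1)
  scen <- run_cohort(st, list(d), toy_mortality(0.2), pifs = pifs)
  av <- dalys_averted(base, scen)
  expect_equal(sum(av$daly), sum(av$yll) + sum(av$yld), tolerance = 1e-12)

  # PIF = 1 removes the only modelled cause entirely: averted YLL equals
  # the closed-form difference between the two life tables
  lt <- function(q) {
    alive <- 1000; yll <- 0
    for (i in 0:4) {
      deaths <- alive * q
      yll <- yll + deaths * (90 - (85 + i))
      alive <- alive - deaths
    }
    yll
  }
  expect_equal(sum(av$yll), lt(0.2) - lt(0.1), tolerance = 1e-9)

  short <- base[base$year < 2028, ]
  class(short) <- class(base)
  expect_error(dalys_averted(base, short), class = "oaoinvest_engine_error")
})

test_that("disease specifications enforce their invariants", {
  rates <- tibble::tibble(age = 0, sex = "male", mortality = 0.1, yld = 0)
  expect_error(disease_spec("x", c(normal = 1.1, overweight = 1.2,
                                   obese = 1.3), rates),
               class = "oaoinvest_disease_error")
  expect_error(disease_spec("x", c(normal = 1, overweight = 2, obese = 1.5),
                            rates),
               class = "oaoinvest_disease_error")
  expect_error(disease_spec("x", c(normal = 1, overweight = 1.2,
                                   obese = 1.3),
                            dplyr::mutate(rates, mortality = -0.1)),
               class = "oaoinvest_disease_error")
})
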