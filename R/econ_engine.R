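# Economic engine: burden streams, discounting, and return on investment.
#
# Health ledgers are converted into annual streams of direct healthcare
# costs (child and adult), wage losses, productivity losses (absenteeism and
# presenteeism), and the economic value of years of life lost (GDP per
# capita times a full-income multiplier, YLLs only). Monetary streams are
# discounted to the index year at a constant annual rate; health outcomes
# are not discounted by default. ROI over a horizon is (discounted benefits
# minus discounted costs) over discounted costs.

#' Economic parameters
#'
#' @param bundle Optional `input_bundle`; its economic tables provide the
#'   defaults, which the remaining arguments override.
#' @param discount_rate Annual discount rate (fraction, default 0.03).
#' @param gdp_multiplier Full-income multiplier converting one year of life
#'   lost into economic value via GDP per capita (default 1.6).
#' @param gdp_per_capita GDP per person-year, local currency.
#' @param exchange_rate Local currency units per USD (default 7.1).
#' @param wage Average annual wage, local currency.
#' @param wage_penalty Fractional lifetime wage loss for adults affected by
#'   child/adolescent overweight or obesity.
#' @param absenteeism_loss Fraction of an affected worker-year's product
#'   lost to absenteeism and presenteeism.
#' @param employment Table (`age`, `rate`) of employment rates.
#' @param healthcare_unit_cost Table (`life_stage`, `category`,
#'   `excess_cost`): annual excess healthcare cost per person by child/adult
#'   stage and overweight/obese status.
#' @param index_year Discounting reference year.
#' @param discount_health Discount DALYs as well as money? Default `FALSE`.
#'
#' @return An object of class `econ_params`.
#' @export
econ_params <- function(bundle = NULL, discount_rate = 0.03,
                        gdp_multiplier = 1.6, gdp_per_capita = NULL,
                        exchange_rate = NULL, wage = NULL,
                        wage_penalty = NULL, absenteeism_loss = NULL,
                        employment = NULL, healthcare_unit_cost = NULL,
                        index_year = NULL, discount_health = FALSE) {
  if (!is.null(bundle)) {
    sc <- setNames(bundle$econ_scalars$value, bundle$econ_scalars$param)
    gdp_per_capita <- gdp_per_capita %||% unname(sc["gdp_per_capita"])
    exchange_rate <- exchange_rate %||% unname(sc["exchange_rate"])
    wage <- wage %||% unname(sc["wage"])
    wage_penalty <- wage_penalty %||% unname(sc["wage_penalty"])
    absenteeism_loss <- absenteeism_loss %||% unname(sc["absenteeism_loss"])
    employment <- employment %||% bundle$employment
    healthcare_unit_cost <- healthcare_unit_cost %||%
      bundle$healthcare_unit_cost
    index_year <- index_year %||% unname(sc["index_year"])
  }
  exchange_rate <- exchange_rate %||% 7.1
  assert_that(is_scalar_number(discount_rate) && discount_rate >= 0,
              "`discount_rate` must be >= 0", "oaoinvest_econ_error")
  assert_that(is_scalar_number(gdp_multiplier) && gdp_multiplier > 0,
              "`gdp_multiplier` must be > 0", "oaoinvest_econ_error")
  for (nm in c("gdp_per_capita", "exchange_rate", "wage")) {
    v <- get(nm)
    assert_that(is_scalar_number(v) && v >= 0,
                paste0("`", nm, "` must be a non-negative number"),
                "oaoinvest_econ_error")
  }
  for (nm in c("wage_penalty", "absenteeism_loss")) {
    v <- get(nm)
    assert_that(is_scalar_number(v) && v >= 0 && v <= 1,
                paste0("`", nm, "` must be a fraction in [0, 1]"),
                "oaoinvest_econ_error")
  }
  assert_that(!is.null(employment) && !is.null(healthcare_unit_cost) &&
                !is.null(index_year),
              "employment, healthcare_unit_cost and index_year are required",
              "oaoinvest_econ_error")
  assert_that(all(healthcare_unit_cost$excess_cost >= 0),
              "unit costs must be non-negative", "oaoinvest_econ_error")
  structure(
    list(discount_rate = discount_rate, gdp_multiplier = gdp_multiplier,
         gdp_per_capita = gdp_per_capita, exchange_rate = exchange_rate,
         wage = wage, wage_penalty = wage_penalty,
         absenteeism_loss = absenteeism_loss,
         employment = tibble::as_tibble(employment),
         healthcare_unit_cost = tibble::as_tibble(healthcare_unit_cost),
         index_year = as.numeric(index_year),
         discount_health = isTRUE(discount_health)),
    class = "econ_params"
  )
}

#' Discount a value (or stream) to the index year
#'
#' `value / (1 + r)^(year - index_year)`.
#'
#' @param value Numeric vector of amounts.
#' @param year Calendar year(s) the amounts occur in (not before the index
#'   year).
#' @param params An [econ_params()].
#' @return Present values at the index year.
#' @export
discount <- function(value, year, params) {
  assert_that(all(year >= params$index_year),
              "cannot discount a year before the index year",
              "oaoinvest_econ_error")
  value / (1 + params$discount_rate)^(year - params$index_year)
}

#' Economic value of years of life lost
#'
#' `YLL x GDP per capita x full-income multiplier`, per year.
#'
#' @param yll Numeric vector of person-years of life lost.
#' @param params An [econ_params()].
#' @return Monetary values, same length as `yll`.
#' @export
mortality_value <- function(yll, params) {
  assert_that(all(yll >= 0), "YLL must be non-negative",
              "oaoinvest_econ_error")
  yll * params$gdp_per_capita * params$gdp_multiplier
}

unit_cost_lookup <- function(params, life_stage, category) {
  uc <- params$healthcare_unit_cost
  v <- uc$excess_cost[uc$life_stage == life_stage & uc$category == category]
  assert_that(length(v) == 1,
              paste0("missing healthcare unit cost for ", life_stage, "/",
                     category),
              "oaoinvest_econ_error")
  v
}

# Join scenario prevalences onto the ledger's person-time table.
person_time_with_prev <- function(states, ledger) {
  pt <- attr(ledger, "person_time")
  assert_that(!is.null(pt), "ledger lacks person-time (rerun run_cohort)",
              "oaoinvest_econ_error")
  idx <- match(paste(pt$age0, pt$sex, pt$year),
               paste(states$age0, states$sex, states$year))
  assert_that(!anyNA(idx), "states do not cover the ledger's person-time",
              "oaoinvest_econ_error")
  pt$prev_overweight <- states$prev_overweight[idx]
  pt$prev_obese <- states$prev_obese[idx]
  pt
}

#' Attributable direct healthcare costs per year, split child/adult
#'
#' Person-years lived times prevalence times the excess unit cost of each
#' weight category; childhood is ages under 20.
#'
#' @param states The scenario's `cohort_states`.
#' @param ledger The scenario's `health_ledger` (supplies survivors).
#' @param params An [econ_params()].
#' @return A tibble (`year`, `healthcare_child`, `healthcare_adult`).
#' @export
healthcare_costs <- function(states, ledger, params) {
  pt <- person_time_with_prev(states, ledger)
  child <- pt$age < 20
  c_ow <- ifelse(child, unit_cost_lookup(params, "child", "overweight"),
                 unit_cost_lookup(params, "adult", "overweight"))
  c_ob <- ifelse(child, unit_cost_lookup(params, "child", "obese"),
                 unit_cost_lookup(params, "adult", "obese"))
  cell <- pt$person_years * (pt$prev_overweight * c_ow + pt$prev_obese * c_ob)
  tibble::tibble(year = pt$year, child = ifelse(child, cell, 0),
                 adult = ifelse(child, 0, cell)) |>
    dplyr::group_by(.data$year) |>
    dplyr::summarise(healthcare_child = sum(.data$child),
                     healthcare_adult = sum(.data$adult),
                     .groups = "drop")
}

#' Wage and productivity losses per year
#'
#' Affected workers are adult person-years with overweight/obesity times the
#' age-specific employment rate. Wage loss applies the fractional wage
#' penalty; productivity loss the absenteeism/presenteeism fraction, both on
#' the average wage.
#'
#' @inheritParams healthcare_costs
#' @return A tibble (`year`, `wage_loss`, `productivity_loss`).
#' @export
wage_and_productivity_losses <- function(states, ledger, params) {
  pt <- person_time_with_prev(states, ledger)
  emp <- params$employment
  rate <- emp$rate[match(pt$age, emp$age)]
  rate[is.na(rate)] <- 0
  workers <- pt$person_years * (pt$prev_overweight + pt$prev_obese) * rate
  workers[pt$age < 20] <- 0
  tibble::tibble(
    year = pt$year,
    wage_loss = workers * params$wage * params$wage_penalty,
    productivity_loss = workers * params$wage * params$absenteeism_loss
  ) |>
    dplyr::group_by(.data$year) |>
    dplyr::summarise(wage_loss = sum(.data$wage_loss),
                     productivity_loss = sum(.data$productivity_loss),
                     .groups = "drop")
}

#' Build the annual economic ledger for one scenario
#'
#' Combines the healthcare, wage, productivity, and mortality-value streams
#' with any intervention cost stream, in local currency at index-year
#' prices, and adds a discounted twin of every stream.
#'
#' @param states The scenario's `cohort_states`.
#' @param ledger The scenario's `health_ledger`.
#' @param params An [econ_params()].
#' @param intervention_cost Optional tibble (`year`, `cost`).
#' @return A tibble of class `econ_ledger`, one row per year, with columns
#'   `healthcare_child`, `healthcare_adult`, `wage_loss`,
#'   `productivity_loss`, `mortality_value`, `intervention_cost` and their
#'   `_disc` twins.
#' @export
build_econ_ledger <- function(states, ledger, params,
                              intervention_cost = NULL) {
  hc <- healthcare_costs(states, ledger, params)
  wp <- wage_and_productivity_losses(states, ledger, params)
  yll_by_year <- ledger |>
    dplyr::group_by(.data$year) |>
    dplyr::summarise(yll = sum(.data$yll), .groups = "drop")
  out <- dplyr::left_join(hc, wp, by = "year") |>
    dplyr::left_join(yll_by_year, by = "year")
  out$mortality_value <- mortality_value(out$yll, params)
  out$yll <- NULL
  if (is.null(intervention_cost)) {
    out$intervention_cost <- 0
  } else {
    idx <- match(out$year, intervention_cost$year)
    out$intervention_cost <- ifelse(is.na(idx), 0,
                                    intervention_cost$cost[idx])
  }
  for (nm in c("healthcare_child", "healthcare_adult", "wage_loss",
               "productivity_loss", "mortality_value",
               "intervention_cost")) {
    out[[paste0(nm, "_disc")]] <- discount(out[[nm]], out$year, params)
  }
  attr(out, "scenario") <- attr(ledger, "scenario")
  attr(out, "index_year") <- params$index_year
  class(out) <- c("econ_ledger", class(out))
  out
}

#' Benefit streams of a scenario relative to baseline
#'
#' Healthcare savings, wage gains, and productivity gains are the baseline
#' minus scenario streams; the economic value of life-years gained is the
#' mortality value of the YLLs averted (YLLs only).
#'
#' @param base_econ,scen_econ `econ_ledger`s for baseline and scenario.
#' @return A tibble (`year`, `healthcare_savings`, `wage_gains`,
#'   `productivity_gains`, `mortality_value_gains`, `total`) in undiscounted
#'   local currency.
#' @export
benefit_streams <- function(base_econ, scen_econ) {
  assert_that(identical(base_econ$year, scen_econ$year),
              "econ ledgers cover different years", "oaoinvest_econ_error")
  out <- tibble::tibble(
    year = base_econ$year,
    healthcare_savings = (base_econ$healthcare_child +
                            base_econ$healthcare_adult) -
      (scen_econ$healthcare_child + scen_econ$healthcare_adult),
    wage_gains = base_econ$wage_loss - scen_econ$wage_loss,
    productivity_gains = base_econ$productivity_loss -
      scen_econ$productivity_loss,
    mortality_value_gains = base_econ$mortality_value -
      scen_econ$mortality_value
  )
  out$total <- out$healthcare_savings + out$wage_gains +
    out$productivity_gains + out$mortality_value_gains
  out
}

#' Return on investment
#'
#' `(benefit - cost) / cost`, both already discounted to the index year.
#'
#' @param benefit_total,cost_total Discounted totals; `cost_total > 0`.
#' @return The ROI ratio.
#' @export
#' @examples
#' roi(12236.4, 526)   # school-based intervention over a lifetime
roi <- function(benefit_total, cost_total) {
  assert_that(all(cost_total > 0), "`cost_total` must be positive",
              "oaoinvest_econ_error")
  (benefit_total - cost_total) / cost_total
}

#' ROI over multiple horizons
#'
#' Sums the discounted benefit and cost streams over the first `h` model
#' years (the index year inclusive) for each horizon, then applies [roi()].
#' `Inf` means the whole model horizon (lifetime).
#'
#' @param benefits Tibble (`year`, `total`) of undiscounted benefits (as
#'   from [benefit_streams()]).
#' @param costs Tibble (`year`, `cost`) of undiscounted costs.
#' @param params An [econ_params()].
#' @param horizons Numeric vector of horizon lengths in years.
#' @return A tibble (`horizon`, `benefit_disc`, `cost_disc`, `roi`).
#' @export
roi_by_horizon <- function(benefits, costs, params,
                           horizons = c(10, 30, 50, Inf)) {
  b_disc <- discount(benefits$total, benefits$year, params)
  c_disc <- discount(costs$cost, costs$year, params)
  rows <- lapply(horizons, function(h) {
    cut <- params$index_year + h
    b <- sum(b_disc[benefits$year < cut])
    cval <- sum(c_disc[costs$year < cut])
    tibble::tibble(horizon = h, benefit_disc = b, cost_disc = cval,
                   roi = if (cval > 0) (b - cval) / cval else NA_real_)
  })
  dplyr::bind_rows(rows)
}
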