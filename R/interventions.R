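# Intervention specifications, coverage ramps, prevalence effects, and cost
# streams.
#
# Each intervention scales up linearly from its baseline coverage to its
# target across the implementation window and stops (coverage 0) after the
# window, when the cohort has aged out of eligibility. Its effect is a
# relative reduction in overweight/obese prevalence among the incrementally
# covered eligible persons (effects already delivered at baseline coverage
# are embedded in the observed baseline epidemiology). Reductions achieved
# in childhood persist into adulthood, attenuated once by a tracking
# coefficient. Policy interventions are costed as fixed annual programme
# costs; person-level interventions per covered person-year.

#' Construct an intervention specification
#'
#' @param name Intervention name.
#' @param target_ages Length-2 vector, inclusive age range of eligibility.
#' @param target_group `"all"` eligible persons, or `"affected"` (only those
#'   with overweight/obesity, e.g. clinical counselling).
#' @param baseline_coverage,target_coverage Fractions in `[0, 1]` with
#'   baseline `<=` target.
#' @param effect Relative reduction in overweight and obese prevalence among
#'   covered persons (`>= 0`).
#' @param unit_cost Cost per covered person-year (`cost_mode = "per_person"`)
#'   or fixed annual programme cost (`cost_mode = "program"`), local
#'   currency at index-year prices.
#' @param cost_mode `"per_person"` or `"program"`.
#' @param window Length-2 vector of calendar years (start, end) of
#'   implementation.
#'
#' @return An object of class `intervention_spec`.
#' @export
intervention_spec <- function(name, target_ages,
                              target_group = c("all", "affected"),
                              baseline_coverage, target_coverage,
                              effect, unit_cost,
                              cost_mode = c("per_person", "program"),
                              window = c(2025, 2044)) {
  target_group <- match.arg(target_group)
  cost_mode <- match.arg(cost_mode)
  assert_that(length(target_ages) == 2 && target_ages[1] <= target_ages[2],
              "`target_ages` must be an ascending age pair",
              "oaoinvest_spec_error")
  assert_that(baseline_coverage >= 0 && target_coverage <= 1 &&
                baseline_coverage <= target_coverage,
              "need 0 <= baseline_coverage <= target_coverage <= 1",
              "oaoinvest_spec_error")
  assert_that(effect >= 0, "`effect` must be >= 0", "oaoinvest_spec_error")
  assert_that(unit_cost >= 0, "`unit_cost` must be >= 0",
              "oaoinvest_spec_error")
  assert_that(length(window) == 2 && window[1] <= window[2],
              "`window` must be an ascending year pair",
              "oaoinvest_spec_error")
  structure(
    list(name = name, target_ages = as.numeric(target_ages),
         target_group = target_group,
         baseline_coverage = baseline_coverage,
         target_coverage = target_coverage, effect = effect,
         unit_cost = unit_cost, cost_mode = cost_mode,
         window = as.numeric(window)),
    class = "intervention_spec"
  )
}

#' Construct an intervention-package specification
#'
#' @param name Package name.
#' @param members Character vector of member intervention names (non-empty,
#'   no duplicates).
#' @param combination_rule `"multiplicative_residual"` (default) or
#'   `"additive_capped"`; see [combine_reductions()].
#' @return An object of class `package_spec`.
#' @export
package_spec <- function(name, members,
                         combination_rule = c("multiplicative_residual",
                                              "additive_capped")) {
  combination_rule <- match.arg(combination_rule)
  assert_that(length(members) >= 1 && !anyDuplicated(members),
              "`members` must be non-empty without duplicates",
              "oaoinvest_spec_error")
  structure(list(name = name, members = members,
                 combination_rule = combination_rule),
            class = "package_spec")
}

#' The default intervention roster
#'
#' Five interventions with their baseline and target coverages: restrictions
#' on unhealthy food marketing to children (ages 2-18, 0 to 80%), mandatory
#' front-of-package labelling (all ages, 5 to 100%), nutrition counselling
#' in primary healthcare for children affected by overweight/obesity
#' (ages 0-19, 0 to 40%), a family-based programme (ages 6-7, 0 to 80%),
#' and a school-based programme (ages 6-17, 5 to 80%), all implemented over
#' a 20-year window starting at the index year. Effect sizes and unit costs
#' are model inputs with package defaults; see the methods vignette.
#'
#' @param index_year First year of implementation (window runs 20 years).
#' @return Named list of [intervention_spec()]s.
#' @export
default_interventions <- function(index_year = 2025) {
  window <- c(index_year, index_year + 19)
  specs <- list(
    intervention_spec("marketing_restrictions", c(2, 18), "all",
                      0.00, 0.80, effect = 0.10,
                      unit_cost = 225000, cost_mode = "program",
                      window = window),
    intervention_spec("fopl", c(0, 19), "all",
                      0.05, 1.00, effect = 0.02,
                      unit_cost = 1325000, cost_mode = "program",
                      window = window),
    intervention_spec("nutrition_counseling", c(0, 19), "affected",
                      0.00, 0.40, effect = 0.15,
                      unit_cost = 50, cost_mode = "per_person",
                      window = window),
    intervention_spec("family_based", c(6, 7), "all",
                      0.00, 0.80, effect = 0.10,
                      unit_cost = 60, cost_mode = "per_person",
                      window = window),
    intervention_spec("school_based", c(6, 17), "all",
                      0.05, 0.80, effect = 0.08,
                      unit_cost = 260, cost_mode = "per_person",
                      window = window)
  )
  setNames(specs, vapply(specs, function(s) s$name, character(1)))
}

#' The default package roster
#'
#' Package 1 combines the two policy interventions (marketing restrictions
#' and FOPL); Package 2 adds the school-based programme and nutrition
#' counselling; `all_five` combines everything.
#'
#' @return Named list of [package_spec()]s.
#' @export
default_packages <- function() {
  pkgs <- list(
    package_spec("package_1", c("marketing_restrictions", "fopl")),
    package_spec("package_2", c("marketing_restrictions", "fopl",
                                "school_based", "nutrition_counseling")),
    package_spec("all_five", c("marketing_restrictions", "fopl",
                               "nutrition_counseling", "family_based",
                               "school_based"))
  )
  setNames(pkgs, vapply(pkgs, function(p) p$name, character(1)))
}

#' Coverage of an intervention in given calendar years
#'
#' Baseline coverage before the window; a linear ramp from baseline to
#' target across the window (reaching the target in the final window year);
#' zero after the window ends, when the cohort has aged out of eligibility.
#'
#' @param spec An [intervention_spec()].
#' @param year Vector of calendar years.
#' @return Coverage fractions, one per year.
#' @export
#' @examples
#' sp <- intervention_spec("m", c(2, 18), "all", 0, 0.8, 0.1, 1,
#'                         window = c(2025, 2044))
#' coverage_path(sp, c(2024, 2035, 2044, 2045))
coverage_path <- function(spec, year) {
  w <- spec$window
  b <- spec$baseline_coverage; tgt <- spec$target_coverage
  ramp <- if (w[2] > w[1]) b + (tgt - b) * (year - w[1]) / (w[2] - w[1])
          else rep(tgt, length(year))
  out <- ifelse(year < w[1], b, ifelse(year > w[2], 0, ramp))
  as.numeric(out)
}

#' Combine per-intervention prevalence reductions
#'
#' `multiplicative_residual` treats reductions as independent survival of
#' the residual risk: combined = `1 - prod(1 - r_i)`. `additive_capped`
#' sums and caps at 1. Additive-capped always dominates the multiplicative
#' rule.
#'
#' @param reductions Numeric vector of fractions in `[0, 1]`.
#' @param rule Combination rule.
#' @return A single combined reduction in `[0, 1]`.
#' @export
combine_reductions <- function(reductions,
                               rule = c("multiplicative_residual",
                                        "additive_capped")) {
  rule <- match.arg(rule)
  assert_that(length(reductions) >= 1, "need at least one reduction",
              "oaoinvest_spec_error")
  assert_that(all(reductions >= 0 & reductions <= 1),
              "reductions must lie in [0, 1]", "oaoinvest_spec_error")
  switch(rule,
         multiplicative_residual = 1 - prod(1 - reductions),
         additive_capped = min(sum(reductions), 1))
}

#' Per-stratum prevalence-reduction streams for a set of interventions
#'
#' For every (cohort stratum, calendar year), computes each intervention's
#' reduction as incremental coverage (coverage above baseline) times effect
#' when the stratum's age is eligible, combines the active reductions with
#' the given rule, and carries the last achieved reduction forward after
#' eligibility ends, attenuated once by the tracking coefficient (the
#' persistence of childhood weight-status improvements into adulthood).
#'
#' @param specs List of [intervention_spec()]s.
#' @param states A `cohort_states` table.
#' @param rule Combination rule, see [combine_reductions()].
#' @param tracking Fraction in `[0, 1]` of the last in-window reduction
#'   retained for life after ageing out (default 0.8).
#' @return A tibble (`age0`, `sex`, `year`, `reduction`).
#' @export
scenario_reductions <- function(specs, states,
                                rule = "multiplicative_residual",
                                tracking = 0.8) {
  assert_that(tracking >= 0 && tracking <= 1,
              "`tracking` must be in [0, 1]", "oaoinvest_spec_error")
  n <- nrow(states)
  if (length(specs) == 0) {
    return(tibble::tibble(age0 = states$age0, sex = states$sex,
                          year = states$year, reduction = 0))
  }
  per_spec <- matrix(0, n, length(specs))
  for (j in seq_along(specs)) {
    s <- specs[[j]]
    eligible <- states$age >= s$target_ages[1] &
      states$age <= s$target_ages[2]
    inc_cov <- pmax(coverage_path(s, states$year) - s$baseline_coverage, 0)
    per_spec[, j] <- ifelse(eligible, inc_cov * s$effect, 0)
  }
  active <- apply(per_spec, 1, combine_reductions, rule = rule)

  df <- tibble::tibble(age0 = states$age0, sex = states$sex,
                       year = states$year, active = active)
  df <- df[order(df$age0, df$sex, df$year), ]
  out <- df |>
    dplyr::group_by(.data$age0, .data$sex) |>
    dplyr::group_modify(function(g, key) {
      # Ratchet: the reduction in force is the larger of the currently
      # active reduction and the tracked (once-attenuated) best reduction
      # achieved so far, so ageing out of one intervention while a weaker
      # one is still active never erases the achieved improvement.
      tibble::tibble(year = g$year,
                     reduction = pmax(g$active,
                                      tracking * cummax(g$active)))
    }) |>
    dplyr::ungroup()
  out
}

#' Apply prevalence reductions to cohort states
#'
#' Scenario prevalences: the overweight and obese masses are each reduced
#' by the stratum-year reduction fraction and the normal-weight category
#' absorbs the difference, so the three prevalences still sum to one.
#'
#' @param states A `cohort_states` table (baseline).
#' @param reductions Tibble (`age0`, `sex`, `year`, `reduction`) as from
#'   [scenario_reductions()], or a single number applied everywhere.
#' @return A `cohort_states` table with scenario prevalences.
#' @export
apply_effect <- function(states, reductions) {
  if (is.numeric(reductions) && length(reductions) == 1) {
    rho <- rep(reductions, nrow(states))
  } else {
    idx <- match(paste(states$age0, states$sex, states$year),
                 paste(reductions$age0, reductions$sex, reductions$year))
    assert_that(!anyNA(idx), "reductions do not cover all cohort states",
                "oaoinvest_spec_error")
    rho <- reductions$reduction[idx]
  }
  assert_that(all(rho >= 0 & rho <= 1),
              "reductions must lie in [0, 1]", "oaoinvest_spec_error")
  out <- states
  out$prev_overweight <- states$prev_overweight * (1 - rho)
  out$prev_obese <- states$prev_obese * (1 - rho)
  out$prev_normal <- 1 - out$prev_overweight - out$prev_obese
  assert_that(all(out$prev_normal >= -1e-12 & out$prev_normal <= 1 + 1e-12),
              "scenario prevalence outside [0, 1]", "oaoinvest_spec_error")
  out
}

#' Annual cost stream of an intervention
#'
#' Per-person mode: incremental covered eligible person-years times the unit
#' cost, where eligible persons are the index-year stratum populations whose
#' current age falls in the target range (for `target_group = "affected"`,
#' scaled by the stratum's overweight+obese prevalence). Programme mode: a
#' fixed annual cost in every window year. Zero outside the window.
#'
#' @param spec An [intervention_spec()].
#' @param states A `cohort_states` table (baseline).
#' @return A tibble (`year`, `cost`) covering all state years.
#' @export
cost_stream <- function(spec, states) {
  years <- sort(unique(states$year))
  cost <- numeric(length(years))
  in_window <- years >= spec$window[1] & years <= spec$window[2]
  if (spec$cost_mode == "program") {
    cost[in_window] <- spec$unit_cost
  } else {
    cov <- pmax(coverage_path(spec, years) - spec$baseline_coverage, 0)
    eligible <- states$age >= spec$target_ages[1] &
      states$age <= spec$target_ages[2]
    w <- states$population[eligible]
    if (spec$target_group == "affected") {
      w <- w * (states$prev_overweight[eligible] +
                  states$prev_obese[eligible])
    }
    elig_by_year <- tapply(w, states$year[eligible], sum)
    idx <- match(years, as.numeric(names(elig_by_year)))
    elig <- ifelse(is.na(idx), 0, elig_by_year[idx])
    cost <- ifelse(in_window, elig * cov * spec$unit_cost, 0)
  }
  assert_that(all(cost >= 0), "negative intervention cost",
              "oaoinvest_spec_error")
  tibble::tibble(year = years, cost = as.numeric(cost))
}

#' Annual cost stream of a set of interventions (package additivity)
#'
#' A package's cost is exactly the sum of its members' cost streams.
#'
#' @param specs List of [intervention_spec()]s.
#' @param states A `cohort_states` table.
#' @return A tibble (`year`, `cost`).
#' @export
cost_stream_total <- function(specs, states) {
  streams <- lapply(specs, cost_stream, states = states)
  out <- streams[[1]]
  if (length(streams) > 1) {
    for (s in streams[-1]) out$cost <- out$cost + s$cost
  }
  out
}

#' Solve for the effect size that reproduces a stated DALY reduction
#'
#' Given an intervention whose effect size is unknown but whose lifetime
#' DALY reduction is reported, finds the relative prevalence reduction that
#' makes the model reproduce that total. DALYs averted are continuous and
#' strictly increasing in the effect, so the root is unique.
#'
#' @param spec An [intervention_spec()] (its `effect` field is ignored).
#' @param target_daly Reported lifetime DALYs averted.
#' @param states Baseline `cohort_states`.
#' @param diseases List of [disease_spec()]s.
#' @param mortality All-cause mortality table.
#' @param base_ledger Optional precomputed baseline `health_ledger`.
#' @param tracking,rule Passed to [scenario_reductions()].
#' @param interval Search interval for the effect.
#' @param tol Root-finding tolerance on the effect.
#' @return The calibrated effect size.
#' @export
calibrate_effect <- function(spec, target_daly, states, diseases, mortality,
                             base_ledger = NULL, tracking = 0.8,
                             rule = "multiplicative_residual",
                             interval = c(0, 1), tol = 1e-10) {
  if (is.null(base_ledger)) {
    base_ledger <- run_cohort(states, diseases, mortality,
                              scenario = "baseline")
  }
  averted_for <- function(effect) {
    s <- spec
    s$effect <- effect
    red <- scenario_reductions(list(s), states, rule = rule,
                               tracking = tracking)
    scen_states <- apply_effect(states, red)
    pifs <- compute_pifs(states, scen_states, diseases)
    led <- run_cohort(states, diseases, mortality, pifs = pifs,
                      scenario = spec$name)
    sum(dalys_averted(base_ledger, led)$daly)
  }
  f <- function(e) averted_for(e) - target_daly
  lo <- f(interval[1]); hi <- f(interval[2])
  assert_that(lo <= 0 && hi >= 0,
              "target DALY reduction is outside the achievable range",
              "oaoinvest_spec_error")
  uniroot(f, interval, tol = tol)$root
}

#' Read intervention and package specifications from a YAML or JSON file
#'
#' The file has two top-level keys, `interventions` (a list of records with
#' the [intervention_spec()] fields) and optionally `packages` (records with
#' `name`, `members`, `combination_rule`). The packaged default
#' configuration is at
#' `system.file("extdata", "interventions.yaml", package = "oaoinvest")`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A list with elements `interventions` and `packages`, both named
#'   lists of spec objects.
#' @export
read_intervention_config <- function(path) {
  assert_that(file.exists(path), paste0("no such file: ", path),
              "oaoinvest_io_error")
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  assert_that(!is.null(raw$interventions),
              "config needs an `interventions` key", "oaoinvest_io_error")
  ints <- lapply(raw$interventions, function(r) {
    intervention_spec(
      name = r$name, target_ages = unlist(r$target_ages),
      target_group = r$target_group %||% "all",
      baseline_coverage = r$baseline_coverage,
      target_coverage = r$target_coverage, effect = r$effect,
      unit_cost = r$unit_cost, cost_mode = r$cost_mode %||% "per_person",
      window = unlist(r$window %||% c(2025, 2044))
    )
  })
  ints <- setNames(ints, vapply(ints, function(s) s$name, character(1)))
  pkgs <- lapply(raw$packages %||% list(), function(r) {
    package_spec(r$name, unlist(r$members),
                 r$combination_rule %||% "multiplicative_residual")
  })
  pkgs <- setNames(pkgs, vapply(pkgs, function(p) p$name, character(1)))
  list(interventions = ints, packages = pkgs)
}
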