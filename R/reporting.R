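# End-to-end orchestration: configuration, validation, scenario runs,
# investment-case output tables, and deterministic run manifests.

#' Run configuration
#'
#' @param seed Seed for the synthetic bundle when no bundle is supplied.
#' @param bundle Optional pre-built `input_bundle`.
#' @param bundle_dir Optional directory to load a written bundle from
#'   (checksums verified); takes precedence over `seed`, and `bundle` over
#'   both.
#' @param synthetic Optional [synthetic_config()] used when generating
#'   (its seed is overridden by `seed` if both are given).
#' @param scenarios Character vector of scenario names: intervention names,
#'   package names, or both. Defaults to the five interventions plus
#'   Package 1, Package 2 and all-five.
#' @param interventions Named list of [intervention_spec()]s.
#' @param packages Named list of [package_spec()]s.
#' @param econ Named list of overrides passed to [econ_params()].
#' @param horizons ROI horizons in years, ascending (`Inf` = lifetime).
#' @param tracking Childhood-to-adulthood persistence coefficient.
#' @param rule Combination rule for standalone multi-intervention scenarios.
#' @param adult_method Adult BMI projection: `"hold"` or `"linear"`.
#' @param half_cycle Mid-cycle death correction in the cohort engine.
#' @param lag Years between a prevalence change and its health effect.
#'
#' @return An object of class `run_config`.
#' @export
run_config <- function(seed = 1, bundle = NULL, bundle_dir = NULL,
                       synthetic = NULL, scenarios = NULL,
                       interventions = NULL, packages = default_packages(),
                       econ = list(), horizons = c(10, 30, 50, Inf),
                       tracking = 0.8, rule = "multiplicative_residual",
                       adult_method = "hold", half_cycle = FALSE, lag = 1) {
  assert_that(!is.unsorted(horizons), "`horizons` must be ascending",
              "oaoinvest_config_error")
  cfg <- list(seed = seed, bundle = bundle, bundle_dir = bundle_dir,
              synthetic = synthetic, scenarios = scenarios,
              interventions = interventions, packages = packages,
              econ = econ, horizons = horizons, tracking = tracking,
              rule = rule, adult_method = adult_method,
              half_cycle = half_cycle, lag = lag)
  structure(cfg, class = "run_config")
}

resolve_bundle <- function(config) {
  if (!is.null(config$bundle)) return(config$bundle)
  if (!is.null(config$bundle_dir)) return(load_bundle(config$bundle_dir))
  sc <- config$synthetic %||% synthetic_config(seed = config$seed)
  if (!is.null(config$seed)) sc$seed <- as.integer(config$seed)
  generate_bundle(sc)
}

resolve_scenarios <- function(config, interventions, packages) {
  names_all <- config$scenarios %||% c(names(interventions), names(packages))
  lapply(setNames(names_all, names_all), function(nm) {
    if (nm %in% names(interventions)) {
      list(name = nm, specs = interventions[nm], rule = config$rule)
    } else if (nm %in% names(packages)) {
      p <- packages[[nm]]
      missing <- setdiff(p$members, names(interventions))
      assert_that(length(missing) == 0,
                  paste0("package `", nm, "` references undefined ",
                         "interventions: ", paste(missing, collapse = ", ")),
                  "oaoinvest_config_error")
      list(name = nm, specs = interventions[p$members],
           rule = p$combination_rule)
    } else {
      abort_oao(paste0("unknown scenario: ", nm), "oaoinvest_config_error")
    }
  })
}

#' Validate an input bundle against the model's invariants
#'
#' Checks relative risks (normal = 1, obese >= overweight >= 1), rate and
#' cost non-negativity, rates within [0, 1], population non-negativity, and
#' BMI-series plausibility. Reports; never raises.
#'
#' @param bundle An `input_bundle` (or anything list-like with its tables).
#' @return A tibble (`check`, `table`, `ok`, `detail`); `detail` locates
#'   offending rows for failed checks.
#' @export
validate_bundle <- function(bundle) {
  checks <- list()
  add <- function(check, table, ok, bad_rows = integer(0)) {
    checks[[length(checks) + 1]] <<- tibble::tibble(
      check = check, table = table, ok = ok,
      detail = if (ok) "" else paste0("rows: ",
                                      paste(utils::head(bad_rows, 10),
                                            collapse = ", "))
    )
  }

  rr <- bundle$disease_rr
  norm_rows <- which(rr$category == "normal" & rr$rr != 1)
  add("rr_normal_is_one", "disease_rr", length(norm_rows) == 0, norm_rows)
  bad <- which(rr$rr < 1)
  add("rr_at_least_one", "disease_rr", length(bad) == 0, bad)
  wide <- tidyr::pivot_wider(rr, names_from = "category",
                             values_from = "rr")
  bad <- which(wide$obese < wide$overweight)
  add("rr_obese_ge_overweight", "disease_rr", length(bad) == 0, bad)

  dr <- bundle$disease_rates
  bad <- which(dr$mortality < 0 | dr$mortality > 1 |
                 dr$yld < 0 | dr$yld > 1)
  add("rates_in_unit_interval", "disease_rates", length(bad) == 0, bad)

  mt <- bundle$mortality
  bad <- which(mt$rate < 0 | mt$rate > 1)
  add("mortality_in_unit_interval", "mortality", length(bad) == 0, bad)

  pop <- bundle$population
  bad <- which(pop$population < 0)
  add("population_non_negative", "population", length(bad) == 0, bad)

  uc <- bundle$healthcare_unit_cost
  bad <- which(uc$excess_cost < 0)
  add("costs_non_negative", "healthcare_unit_cost", length(bad) == 0, bad)

  bs <- bundle$bmi_series
  bad <- which(bs$mean_bmi <= 5 | bs$mean_bmi >= 80)
  add("bmi_plausible", "bmi_series", length(bad) == 0, bad)

  emp <- bundle$employment
  bad <- which(emp$rate < 0 | emp$rate > 1)
  add("employment_in_unit_interval", "employment", length(bad) == 0, bad)

  dplyr::bind_rows(checks)
}

#' Check a cohort-state table's invariants
#'
#' Prevalences in [0, 1] summing to one, positive BMI dispersion,
#' non-negative populations. Reports; never raises.
#'
#' @param states A `cohort_states` table.
#' @return A tibble (`check`, `table`, `ok`, `detail`).
#' @export
validate_states <- function(states) {
  s <- states$prev_normal + states$prev_overweight + states$prev_obese
  bad_sum <- which(abs(s - 1) > 1e-9)
  bad_rng <- which(states$prev_normal < 0 | states$prev_overweight < 0 |
                     states$prev_obese < 0 | states$prev_normal > 1 |
                     states$prev_overweight > 1 | states$prev_obese > 1)
  bad_sd <- which(states$bmi_sd <= 0)
  bad_pop <- which(states$population < 0)
  loc <- function(i) if (length(i) == 0) "" else
    paste0("rows: ", paste(utils::head(i, 10), collapse = ", "))
  tibble::tibble(
    check = c("prevalence_sums_to_one", "prevalence_in_unit_interval",
              "bmi_sd_positive", "population_non_negative"),
    table = "cohort_states",
    ok = c(length(bad_sum) == 0, length(bad_rng) == 0,
           length(bad_sd) == 0, length(bad_pop) == 0),
    detail = c(loc(bad_sum), loc(bad_rng), loc(bad_sd), loc(bad_pop))
  )
}

#' Run the full model for all configured scenarios
#'
#' Generates or loads the input bundle, fits BMI trends, builds the baseline
#' cohort, runs the Markov engine for the baseline and every scenario, and
#' assembles the output tables: baseline health outcomes by sex, the
#' baseline economic burden decomposition, intervention costs, DALY
#' reductions, the savings decomposition, and ROI by horizon.
#'
#' @param config A [run_config()].
#' @return A list of class `model_run`: `bundle`, `params`, `states`,
#'   `baseline` (ledger + econ), `scenarios` (per-scenario details),
#'   `tables` (the six output tables), and `manifest`.
#' @export
run_model <- function(config = run_config()) {
  assert_that(inherits(config, "run_config"),
              "`config` must come from run_config()",
              "oaoinvest_config_error")
  bundle <- resolve_bundle(config)
  interventions <- config$interventions %||%
    default_interventions(bundle$config$index_year)
  scen_defs <- resolve_scenarios(config, interventions, config$packages)

  trends <- fit_bmi_trends(bundle$bmi_series)
  states <- build_cohort_states(bundle, trends,
                                adult_method = config$adult_method)
  diseases <- as_disease_specs(bundle)
  params <- do.call(econ_params, c(list(bundle = bundle), config$econ))

  base_ledger <- run_cohort(states, diseases, bundle$mortality,
                            scenario = "baseline",
                            half_cycle = config$half_cycle)
  base_econ <- build_econ_ledger(states, base_ledger, params)

  # Burden attributable to overweight/obesity: baseline minus the
  # all-normal-weight counterfactual (PIF with all excess mass removed,
  # no implementation lag for a counterfactual).
  null_states <- apply_effect(states, 1)
  null_pifs <- compute_pifs(states, null_states, diseases, lag = 0)
  null_ledger <- run_cohort(states, diseases, bundle$mortality,
                            pifs = null_pifs, scenario = "no_oao",
                            half_cycle = config$half_cycle)
  attrib <- dalys_averted(base_ledger, null_ledger)

  scenarios <- lapply(scen_defs, function(def) {
    red <- scenario_reductions(def$specs, states, rule = def$rule,
                               tracking = config$tracking)
    scen_states <- apply_effect(states, red)
    pifs <- compute_pifs(states, scen_states, diseases, lag = config$lag)
    ledger <- run_cohort(states, diseases, bundle$mortality, pifs = pifs,
                         scenario = def$name,
                         half_cycle = config$half_cycle)
    econ <- build_econ_ledger(scen_states, ledger, params)
    costs <- cost_stream_total(def$specs, states)
    averted <- dalys_averted(base_ledger, ledger)
    benefits <- benefit_streams(base_econ, econ)
    roi_tbl <- roi_by_horizon(benefits, costs, params,
                              horizons = config$horizons)
    list(name = def$name, specs = def$specs, ledger = ledger, econ = econ,
         costs = costs, averted = averted, benefits = benefits,
         roi = roi_tbl)
  })

  tables <- build_output_tables(base_ledger, base_econ, attrib, scenarios,
                                params)
  manifest <- build_manifest(config, bundle, tables)

  structure(
    list(bundle = bundle, params = params, states = states,
         trends = trends, baseline = list(ledger = base_ledger,
                                          econ = base_econ),
         attributable = attrib, scenarios = scenarios, tables = tables,
         manifest = manifest),
    class = "model_run"
  )
}

build_output_tables <- function(base_ledger, base_econ, attrib, scenarios,
                                params) {
  xr <- params$exchange_rate

  # -- health outcomes by sex: burden attributable to overweight/obesity --
  by_sex <- attrib |>
    dplyr::group_by(.data$sex) |>
    dplyr::summarise(yll = sum(.data$yll), yld = sum(.data$yld),
                     daly = sum(.data$daly), .groups = "drop")
  health_outcomes <- dplyr::bind_rows(
    by_sex,
    tibble::tibble(sex = "total", yll = sum(by_sex$yll),
                   yld = sum(by_sex$yld), daly = sum(by_sex$daly))
  )

  # -- baseline burden decomposition, undiscounted and discounted --
  # Healthcare, wage and productivity streams are excess (attributable)
  # costs by construction; mortality value uses the attributable YLLs.
  attrib_yll <- attrib |>
    dplyr::group_by(.data$year) |>
    dplyr::summarise(yll = sum(.data$yll), .groups = "drop")
  # (per-year attributable YLL can be negative late in the horizon when
  # averted deaths are deferred, so value the stream directly)
  mv <- attrib_yll$yll * params$gdp_per_capita * params$gdp_multiplier
  mv_disc <- discount(mv, attrib_yll$year, params)
  sum_pair <- function(u, d) c(sum(u), sum(d))
  rows <- list(
    healthcare_child = sum_pair(base_econ$healthcare_child,
                                base_econ$healthcare_child_disc),
    healthcare_adult = sum_pair(base_econ$healthcare_adult,
                                base_econ$healthcare_adult_disc),
    wage_loss = sum_pair(base_econ$wage_loss, base_econ$wage_loss_disc),
    productivity_loss = sum_pair(base_econ$productivity_loss,
                                 base_econ$productivity_loss_disc),
    mortality_value = sum_pair(mv, mv_disc)
  )
  burden <- tibble::tibble(
    component = names(rows),
    cny = unname(vapply(rows, `[`, numeric(1), 1)),
    cny_disc = unname(vapply(rows, `[`, numeric(1), 2))
  )
  direct <- burden$component %in% c("healthcare_child", "healthcare_adult")
  burden <- dplyr::bind_rows(
    burden,
    tibble::tibble(component = "total_direct",
                   cny = sum(burden$cny[direct]),
                   cny_disc = sum(burden$cny_disc[direct])),
    tibble::tibble(component = "total_indirect",
                   cny = sum(burden$cny[!direct]),
                   cny_disc = sum(burden$cny_disc[!direct])),
    tibble::tibble(component = "total",
                   cny = sum(burden$cny[1:5]),
                   cny_disc = sum(burden$cny_disc[1:5]))
  )
  burden$usd <- burden$cny / xr
  burden$usd_disc <- burden$cny_disc / xr

  # -- intervention cost table --
  costs <- dplyr::bind_rows(lapply(scenarios, function(s) {
    d <- discount(s$costs$cost, s$costs$year, params)
    tibble::tibble(scenario = s$name, cost_cny = sum(s$costs$cost),
                   cost_cny_disc = sum(d))
  }))
  if (nrow(costs) > 0) {
    costs$cost_usd <- costs$cost_cny / xr
    costs$cost_usd_disc <- costs$cost_cny_disc / xr
  }

  # -- DALY reductions --
  daly_reduction <- dplyr::bind_rows(lapply(scenarios, function(s) {
    tibble::tibble(scenario = s$name, dalys_averted = sum(s$averted$daly),
                   yll_averted = sum(s$averted$yll),
                   yld_averted = sum(s$averted$yld))
  }))

  # -- savings decomposition (lifetime, discounted) --
  savings <- dplyr::bind_rows(lapply(scenarios, function(s) {
    d <- function(v) sum(discount(v, s$benefits$year, params))
    tibble::tibble(
      scenario = s$name,
      healthcare_savings = d(s$benefits$healthcare_savings),
      wage_gains = d(s$benefits$wage_gains),
      productivity_gains = d(s$benefits$productivity_gains),
      mortality_value_gains = d(s$benefits$mortality_value_gains)
    )
  }))
  if (nrow(savings) > 0) {
    savings$total <- savings$healthcare_savings + savings$wage_gains +
      savings$productivity_gains + savings$mortality_value_gains
    for (nm in c("healthcare_savings", "wage_gains", "productivity_gains",
                 "mortality_value_gains", "total")) {
      savings[[paste0(nm, "_usd")]] <- savings[[nm]] / xr
    }
  }

  # -- ROI by horizon --
  roi_tbl <- dplyr::bind_rows(lapply(scenarios, function(s) {
    dplyr::mutate(s$roi, scenario = s$name, .before = 1)
  }))

  list(health_outcomes = health_outcomes, burden = burden,
       intervention_costs = costs, daly_reduction = daly_reduction,
       savings = savings, roi = roi_tbl)
}

table_md5 <- function(df) {
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  write.csv(format_full_precision(as.data.frame(df)), path,
            row.names = FALSE, quote = FALSE)
  unname(tools::md5sum(path))
}

build_manifest <- function(config, bundle, tables) {
  cfg_for_hash <- unclass(config)
  cfg_for_hash$bundle <- NULL  # hashed via its tables below
  cfg_json <- tempfile(fileext = ".json")
  on.exit(unlink(cfg_json))
  writeLines(jsonlite::toJSON(cfg_for_hash, auto_unbox = TRUE, digits = NA,
                              force = TRUE), cfg_json)
  list(
    package_version = as.character(utils::packageVersion("oaoinvest")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config_hash = unname(tools::md5sum(cfg_json)),
    seed = bundle$config$seed,
    input_checksums = lapply(
      setNames(bundle_table_names(), bundle_table_names()),
      function(nm) table_md5(bundle[[nm]])
    ),
    output_checksums = lapply(tables, table_md5)
  )
}

#' Write a model run's tables, manifest and log to a directory
#'
#' Tables are CSV at full numeric precision (rounding is for display only);
#' the manifest is JSON; the log records the effective value of every
#' parameter that applied to the run.
#'
#' @param run A `model_run` from [run_model()].
#' @param directory Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
write_outputs <- function(run, directory) {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (nm in names(run$tables)) {
    path <- file.path(directory, paste0(nm, ".csv"))
    write.csv(format_full_precision(as.data.frame(run$tables[[nm]])), path,
              row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
    files <- c(files, path)
  }
  man_path <- file.path(directory, "run_manifest.json")
  jsonlite::write_json(run$manifest, man_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  files <- c(files, man_path)

  p <- run$params
  log_lines <- c(
    paste0("oaoinvest run ", run$manifest$timestamp),
    paste0("seed: ", run$bundle$config$seed),
    paste0("index_year: ", p$index_year),
    paste0("discount_rate: ", p$discount_rate),
    paste0("gdp_multiplier: ", p$gdp_multiplier),
    paste0("gdp_per_capita: ", p$gdp_per_capita),
    paste0("exchange_rate: ", p$exchange_rate),
    paste0("wage: ", p$wage),
    paste0("wage_penalty: ", p$wage_penalty),
    paste0("absenteeism_loss: ", p$absenteeism_loss),
    paste0("discount_health: ", p$discount_health),
    paste0("scenarios: ",
           paste(vapply(run$scenarios, function(s) s$name, character(1)),
                 collapse = ", "))
  )
  log_path <- file.path(directory, "run.log")
  writeLines(log_lines, log_path)
  invisible(c(files, log_path))
}

#' One-way sensitivity grid over economic and effect parameters
#'
#' Re-runs the model at each grid point and reports the lifetime ROI per
#' scenario. The base case is reproduced at the default setting.
#'
#' @param config A [run_config()].
#' @param vary Named list of vectors to vary: any of `discount_rate`,
#'   `gdp_multiplier`, `effect_multiplier` (scales every intervention's
#'   effect).
#' @return A tibble: one row per (grid point, scenario) with the varied
#'   values and `roi_lifetime`.
#' @export
sensitivity_grid <- function(config, vary = list()) {
  known <- c("discount_rate", "gdp_multiplier", "effect_multiplier")
  assert_that(length(vary) > 0 && all(names(vary) %in% known),
              paste0("`vary` must name some of: ",
                     paste(known, collapse = ", ")),
              "oaoinvest_config_error")
  assert_that(all(vapply(vary, function(v) all(is.finite(v)) &&
                           all(v >= 0), logical(1))),
              "grid values must be finite and non-negative",
              "oaoinvest_config_error")
  grid <- do.call(tidyr::expand_grid, vary)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    cfg <- config
    if ("discount_rate" %in% names(grid)) {
      cfg$econ$discount_rate <- grid$discount_rate[i]
    }
    if ("gdp_multiplier" %in% names(grid)) {
      cfg$econ$gdp_multiplier <- grid$gdp_multiplier[i]
    }
    if ("effect_multiplier" %in% names(grid)) {
      ints <- cfg$interventions %||% default_interventions()
      cfg$interventions <- lapply(ints, function(s) {
        s$effect <- s$effect * grid$effect_multiplier[i]
        s
      })
    }
    cfg$horizons <- c(Inf)
    run <- run_model(cfg)
    out <- run$tables$roi[, c("scenario", "roi")]
    names(out)[2] <- "roi_lifetime"
    dplyr::bind_cols(grid[rep(i, nrow(out)), , drop = FALSE], out)
  })
  dplyr::bind_rows(rows)
}

#' Bar chart of the lifetime savings decomposition by scenario
#'
#' @param run A `model_run`.
#' @param usd Plot USD (default) or local-currency values.
#' @return A ggplot object.
#' @export
plot_savings <- function(run, usd = TRUE) {
  sv <- run$tables$savings
  cols <- if (usd) {
    c("healthcare_savings_usd", "wage_gains_usd", "productivity_gains_usd",
      "mortality_value_gains_usd")
  } else {
    c("healthcare_savings", "wage_gains", "productivity_gains",
      "mortality_value_gains")
  }
  long <- tidyr::pivot_longer(sv[, c("scenario", cols)],
                              dplyr::all_of(cols),
                              names_to = "component", values_to = "value")
  long$component <- sub("_usd$", "", long$component)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$scenario, y = .data$value,
                                     fill = .data$component)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL,
                  y = if (usd) "Lifetime savings (USD)" else
                    "Lifetime savings (local currency)",
                  fill = NULL) +
    ggplot2::theme_minimal()
}
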