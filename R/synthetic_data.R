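# Synthetic input bundles with known ground truth.
#
# The generator emulates the statistical structure of the inputs a city-level
# investment case draws on: a closed cohort population by single year of age
# and sex, historical mean-BMI series by age group (NCD-RisC style), cause-
# specific mortality and YLD rates by age and sex (GBD style), relative risks
# of obesity-related causes by weight category, and unit costs. Every stream
# is parameterised and seeded, so downstream stages can be tested against the
# parameters that generated their inputs.

#' Configuration for the synthetic input-bundle generator
#'
#' Defines the study conditions a generated bundle encodes: the index year
#' and cohort ages, the linear time trends in mean BMI by life stage and sex,
#' the within-stratum BMI dispersion, the roster of obesity-related causes
#' and their relative-risk range, and the economic scale factors.
#'
#' @param seed Integer seed; fully determines the bundle (same seed, same
#'   bundle, byte for byte once written).
#' @param index_year Calendar year the cohort is enumerated (cohort ages
#'   0-19 in this year).
#' @param max_age Maximum attainable age; the cohort is extinct once every
#'   member has reached it.
#' @param child_slope,adult_slope Linear trend in mean BMI, kg/m^2 per
#'   calendar year, for childhood (ages 0-19) and adult 5-year age bands.
#'   Either a single number or a named vector `c(male =, female =)`.
#' @param noise_sd Standard deviation, kg/m^2, of the Gaussian noise added
#'   around the linear trend in the historical series.
#' @param bmi_sd_fraction Coefficient of variation of BMI within a stratum:
#'   the BMI standard deviation is this fraction of the mean.
#' @param n_hist_years Number of historical years in each mean-BMI series,
#'   ending at `index_year - 1`.
#' @param disease_count Number of synthetic obesity-related causes.
#' @param rr_range Length-2 vector, both `>= 1`: the range the overweight
#'   and obese relative risks are drawn from (obese >= overweight always).
#' @param pop_mean Mean population per single-year age/sex cell.
#' @param cost_scale Multiplier applied to all generated unit costs.
#' @param exchange_rate Local currency units per USD.
#' @param gdp_per_capita GDP per person-year, local currency, index-year
#'   prices.
#' @param wage Average annual wage, local currency.
#' @param wage_penalty Fractional lifetime wage loss for adults affected by
#'   child/adolescent overweight or obesity.
#' @param absenteeism_loss Fraction of an affected worker-year's product
#'   lost to absenteeism and presenteeism.
#'
#' @return An object of class `synthetic_config`.
#' @export
#' @examples
#' cfg <- synthetic_config(seed = 1)
#' bundle <- generate_bundle(cfg)
synthetic_config <- function(seed = 1L,
                             index_year = 2025,
                             max_age = 90,
                             child_slope = c(male = 0.060, female = 0.055),
                             adult_slope = c(male = 0.045, female = 0.040),
                             noise_sd = 0.1,
                             bmi_sd_fraction = 0.12,
                             n_hist_years = 25,
                             disease_count = 6,
                             rr_range = c(1.2, 3.0),
                             pop_mean = 75000,
                             cost_scale = 1,
                             exchange_rate = 7.1,
                             gdp_per_capita = 190000,
                             wage = 120000,
                             wage_penalty = 0.05,
                             absenteeism_loss = 0.03) {
  assert_that(is_scalar_number(seed) && seed == round(seed),
              "`seed` must be a single integer", "oaoinvest_config_error")
  assert_that(is_scalar_number(index_year) && index_year > 1900,
              "`index_year` must be a calendar year", "oaoinvest_config_error")
  assert_that(is_scalar_number(max_age) && max_age > 20,
              "`max_age` must exceed 20 years", "oaoinvest_config_error")
  assert_that(is_scalar_number(noise_sd) && noise_sd >= 0,
              "`noise_sd` must be >= 0", "oaoinvest_config_error")
  assert_that(is_scalar_number(bmi_sd_fraction) && bmi_sd_fraction > 0,
              "`bmi_sd_fraction` must be > 0", "oaoinvest_config_error")
  assert_that(is_scalar_number(n_hist_years) && n_hist_years >= 3,
              "`n_hist_years` must be >= 3", "oaoinvest_config_error")
  assert_that(is_scalar_number(disease_count) && disease_count >= 1,
              "`disease_count` must be >= 1", "oaoinvest_config_error")
  assert_that(is.numeric(rr_range) && length(rr_range) == 2 &&
                all(rr_range >= 1) && rr_range[1] <= rr_range[2],
              "`rr_range` must be two values >= 1, low <= high",
              "oaoinvest_config_error")
  for (nm in c("pop_mean", "cost_scale", "exchange_rate", "gdp_per_capita",
               "wage")) {
    v <- get(nm)
    assert_that(is_scalar_number(v) && v >= 0,
                paste0("`", nm, "` must be a non-negative number"),
                "oaoinvest_config_error")
  }
  for (nm in c("wage_penalty", "absenteeism_loss")) {
    v <- get(nm)
    assert_that(is_scalar_number(v) && v >= 0 && v <= 1,
                paste0("`", nm, "` must be a fraction in [0, 1]"),
                "oaoinvest_config_error")
  }

  cfg <- list(
    seed = as.integer(seed),
    index_year = as.numeric(index_year),
    max_age = as.numeric(max_age),
    child_slope = expand_by_sex(child_slope),
    adult_slope = expand_by_sex(adult_slope),
    noise_sd = noise_sd,
    bmi_sd_fraction = bmi_sd_fraction,
    n_hist_years = as.integer(n_hist_years),
    disease_count = as.integer(disease_count),
    rr_range = as.numeric(rr_range),
    pop_mean = pop_mean,
    cost_scale = cost_scale,
    exchange_rate = exchange_rate,
    gdp_per_capita = gdp_per_capita,
    wage = wage,
    wage_penalty = wage_penalty,
    absenteeism_loss = absenteeism_loss
  )
  structure(cfg, class = "synthetic_config")
}

expand_by_sex <- function(x) {
  if (length(x) == 1L) x <- c(male = unname(x), female = unname(x))
  assert_that(is.numeric(x) && length(x) == 2 &&
                all(c("male", "female") %in% names(x)),
              "slopes must be a scalar or a named c(male =, female =) vector",
              "oaoinvest_config_error")
  x[c("male", "female")]
}

# Smooth, plausible cross-sectional mean BMI at the start of the historical
# window; children sit a little above the growth-reference median, adults
# plateau in midlife.
baseline_mean_bmi <- function(age_lo, sex) {
  child <- age_lo < 20
  out <- numeric(length(age_lo))
  if (any(child)) {
    ref <- growth_reference_values(age_lo[child], sex[child])
    out[child] <- ref$median + 0.5
  }
  if (any(!child)) {
    a <- age_lo[!child]
    base <- 22.3 + 2.4 * (1 - exp(-(a - 20) / 22)) -
      0.012 * pmax(0, a - 65)^1.2
    base <- base + ifelse(sex[!child] == "male", 0.2, 0)
    out[!child] <- base
  }
  out
}

#' Generate a synthetic input bundle
#'
#' Produces every table the modelling pipeline consumes, plus the ground-truth
#' parameters used to generate them (trend slopes, relative risks) so that
#' parameter-recovery tests can compare fitted values against the truth.
#'
#' @param config A [synthetic_config()] object.
#'
#' @return An object of class `input_bundle`: a list of tibbles
#'   (`population`, `bmi_series`, `disease_rr`, `disease_rates`,
#'   `mortality`, `econ_scalars`, `healthcare_unit_cost`, `employment`)
#'   plus `config` and `ground_truth`.
#' @export
generate_bundle <- function(config) {
  assert_that(inherits(config, "synthetic_config"),
              "`config` must be created by synthetic_config()",
              "oaoinvest_config_error")
  with_local_seed(config$seed, {
    sexes <- c("male", "female")
    hist_years <- seq(config$index_year - config$n_hist_years,
                      config$index_year - 1)

    # --- strata for the BMI series: single ages 0-19, adult 5-year bands ---
    child_strata <- expand.grid(age_lo = 0:19, sex = sexes,
                                stringsAsFactors = FALSE)
    child_strata$age_group <- sprintf("%02d", child_strata$age_lo)
    adult_lo <- seq(20, 5 * floor((config$max_age - 1) / 5), by = 5)
    adult_strata <- expand.grid(age_lo = adult_lo, sex = sexes,
                                stringsAsFactors = FALSE)
    adult_strata$age_group <- sprintf("%d-%d", adult_strata$age_lo,
                                      adult_strata$age_lo + 4)
    strata <- rbind(child_strata, adult_strata)
    strata$slope <- ifelse(
      strata$age_lo < 20,
      config$child_slope[strata$sex],
      config$adult_slope[strata$sex]
    )
    strata$level_start <- baseline_mean_bmi(strata$age_lo, strata$sex)

    series <- tidyr::expand_grid(
      strata[, c("age_group", "age_lo", "sex", "slope", "level_start")],
      year = as.numeric(hist_years)
    )
    series$mean_bmi <- series$level_start +
      series$slope * (series$year - hist_years[1]) +
      rnorm(nrow(series), sd = config$noise_sd)
    bmi_series <- tibble::as_tibble(
      series[, c("age_group", "age_lo", "sex", "year", "mean_bmi")]
    )
    bmi_series$age_lo <- as.numeric(bmi_series$age_lo)

    ground_truth_trends <- tibble::as_tibble(
      unique(series[, c("age_group", "age_lo", "sex", "slope", "level_start")])
    )
    ground_truth_trends$intercept <- ground_truth_trends$level_start -
      ground_truth_trends$slope * hist_years[1]
    ground_truth_trends$level_start <- NULL
    ground_truth_trends$age_lo <- as.numeric(ground_truth_trends$age_lo)

    # --- cohort population at the index year ---
    pop <- tidyr::expand_grid(age = as.numeric(0:19), sex = sexes)
    pop$population <- round(config$pop_mean * runif(nrow(pop), 0.92, 1.08))
    population <- tibble::as_tibble(pop)

    # --- disease roster: relative risks and baseline rates ---
    nd <- config$disease_count
    lo <- config$rr_range[1]; hi <- config$rr_range[2]
    rr_ow <- runif(nd, lo, lo + 0.6 * (hi - lo))
    rr_ob <- rr_ow + runif(nd) * (hi - rr_ow)
    disease_names <- sprintf("cause_%02d", seq_len(nd))
    disease_rr <- tibble::tibble(
      disease = rep(disease_names, each = 3),
      category = rep(wt_categories(), nd),
      rr = as.numeric(t(cbind(1, rr_ow, rr_ob)))
    )

    ages <- as.numeric(0:(config$max_age - 1))
    mort_grid <- tidyr::expand_grid(age = ages, sex = sexes)
    all_cause <- all_cause_mortality(mort_grid$age, mort_grid$sex)
    mortality <- tibble::as_tibble(
      cbind(mort_grid, rate = pmin(all_cause, 0.99))
    )

    # Modelled causes claim an age-increasing share (<= 35%) of all-cause
    # mortality, split across diseases by random weights; the residual is
    # background mortality, so it is non-negative by construction.
    w <- runif(nd, 0.3, 1)
    w <- w / sum(w)
    dw <- runif(nd, 0.5, 1.5)
    disease_rates <- tidyr::expand_grid(
      disease = disease_names, age = ages, sex = sexes
    )
    share <- 0.35 / (1 + exp(-(disease_rates$age - 45) / 8))
    base_q <- pmin(all_cause_mortality(disease_rates$age, disease_rates$sex),
                   0.99)
    disease_rates$mortality <- base_q * share * w[
      match(disease_rates$disease, disease_names)
    ]
    disease_rates$yld <- 0.004 * dw[match(disease_rates$disease,
                                          disease_names)] /
      (1 + exp(-(disease_rates$age - 40) / 10))
    disease_rates <- tibble::as_tibble(disease_rates)

    # --- unit costs and labour-market parameters ---
    healthcare_unit_cost <- tibble::tibble(
      life_stage = rep(c("child", "adult"), each = 2),
      category = rep(c("overweight", "obese"), 2),
      excess_cost = config$cost_scale * c(300, 800, 1000, 2500)
    )
    employment <- tibble::tibble(age = ages)
    employment$rate <- ifelse(employment$age < 20, 0,
                       ifelse(employment$age < 60, 0.78,
                       ifelse(employment$age < 65, 0.25, 0)))

    econ_scalars <- tibble::tibble(
      param = c("index_year", "max_age", "bmi_sd_fraction", "exchange_rate",
                "gdp_per_capita", "wage", "wage_penalty", "absenteeism_loss"),
      value = c(config$index_year, config$max_age, config$bmi_sd_fraction,
                config$exchange_rate, config$gdp_per_capita, config$wage,
                config$wage_penalty, config$absenteeism_loss)
    )

    bundle <- list(
      config = config,
      population = population,
      bmi_series = bmi_series,
      disease_rr = disease_rr,
      disease_rates = disease_rates,
      mortality = mortality,
      econ_scalars = econ_scalars,
      healthcare_unit_cost = healthcare_unit_cost,
      employment = employment,
      ground_truth = list(
        trends = ground_truth_trends,
        rr = tibble::tibble(disease = disease_names,
                            rr_overweight = rr_ow, rr_obese = rr_ob)
      )
    )
    structure(bundle, class = "input_bundle")
  })
}

# Smooth all-cause annual death probability: infant mortality hump, low
# plateau in childhood, Gompertz rise in adulthood; mild male excess.
all_cause_mortality <- function(age, sex) {
  q <- 0.003 * exp(-age / 2) + 2e-4 + 3.5e-5 * exp(0.09 * age)
  q * ifelse(sex == "male", 1.10, 0.90)
}

#' @export
print.input_bundle <- function(x, ...) {
  cat("<input_bundle>\n")
  cat("  index year:", x$config$index_year,
      " seed:", x$config$seed, "\n")
  cat("  cohort:", sum(x$population$population), "persons, ages 0-19\n")
  cat("  BMI series:", length(unique(paste(x$bmi_series$age_group,
                                           x$bmi_series$sex))),
      "strata x", length(unique(x$bmi_series$year)), "years\n")
  cat("  diseases:", length(unique(x$disease_rr$disease)), "\n")
  invisible(x)
}

bundle_table_names <- function() {
  c("population", "bmi_series", "disease_rr", "disease_rates", "mortality",
    "econ_scalars", "healthcare_unit_cost", "employment")
}

# Format numeric columns so they survive a text round trip bit-for-bit.
format_full_precision <- function(df) {
  for (nm in names(df)) {
    if (is.numeric(df[[nm]])) df[[nm]] <- sprintf("%.17g", df[[nm]])
  }
  df
}

bundle_character_cols <- function() {
  c("age_group", "sex", "disease", "category", "param", "life_stage")
}

restore_numeric <- function(df) {
  chr <- bundle_character_cols()
  for (nm in names(df)) {
    df[[nm]] <- if (nm %in% chr) as.character(df[[nm]]) else
      as.numeric(df[[nm]])
  }
  tibble::as_tibble(df)
}

#' Write an input bundle to a directory of delimited files
#'
#' One UTF-8 comma-delimited file per table (full numeric precision, so the
#' bundle round-trips losslessly through [load_bundle()]), plus a JSON
#' manifest recording the generator configuration and an MD5 checksum per
#' file. Ground-truth tables are written alongside for recovery tests.
#'
#' @param bundle An `input_bundle`.
#' @param directory Path to a writable directory (created if absent).
#'
#' @return Invisibly, the manifest as a list.
#' @export
write_bundle <- function(bundle, directory) {
  assert_that(inherits(bundle, "input_bundle"),
              "`bundle` must be an input_bundle", "oaoinvest_io_error")
  tbls <- bundle_table_names()
  for (nm in tbls) {
    assert_that(!is.null(bundle[[nm]]) && nrow(bundle[[nm]]) > 0,
                paste0("bundle table `", nm, "` is missing or empty"),
                "oaoinvest_io_error")
  }
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  assert_that(dir.exists(directory), "cannot create bundle directory",
              "oaoinvest_io_error")

  files <- character(0)
  write_one <- function(df, fname) {
    path <- file.path(directory, fname)
    write.csv(format_full_precision(as.data.frame(df)), path,
              row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
    files[[fname]] <<- unname(tools::md5sum(path))
  }
  for (nm in tbls) write_one(bundle[[nm]], paste0(nm, ".csv"))
  write_one(bundle$ground_truth$trends, "ground_truth_trends.csv")
  write_one(bundle$ground_truth$rr, "ground_truth_rr.csv")

  cfg <- unclass(bundle$config)
  # keep the sex names through JSON (named atomic vectors lose them)
  cfg$child_slope <- as.list(cfg$child_slope)
  cfg$adult_slope <- as.list(cfg$adult_slope)
  manifest <- list(
    format = "oaoinvest-bundle-v1",
    seed = bundle$config$seed,
    index_year = bundle$config$index_year,
    config = cfg,
    files = as.list(files)
  )
  jsonlite::write_json(manifest, file.path(directory, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Load an input bundle written by [write_bundle()]
#'
#' Verifies every file's MD5 checksum against the manifest before reading;
#' a mismatch (tampered or truncated file) is an error.
#'
#' @param directory Path containing `manifest.json` and the bundle tables.
#' @return An `input_bundle`.
#' @export
load_bundle <- function(directory) {
  man_path <- file.path(directory, "manifest.json")
  assert_that(file.exists(man_path), "no manifest.json in directory",
              "oaoinvest_io_error")
  manifest <- jsonlite::read_json(man_path, simplifyVector = TRUE)
  assert_that(identical(manifest$format, "oaoinvest-bundle-v1"),
              "unrecognised bundle format", "oaoinvest_io_error")

  for (fname in names(manifest$files)) {
    path <- file.path(directory, fname)
    assert_that(file.exists(path), paste0("missing bundle file: ", fname),
                "oaoinvest_io_error")
    sum_now <- unname(tools::md5sum(path))
    assert_that(identical(sum_now, manifest$files[[fname]]),
                paste0("checksum mismatch for ", fname,
                       ": file differs from manifest"),
                "oaoinvest_io_error")
  }

  read_one <- function(fname) {
    restore_numeric(read.csv(file.path(directory, fname),
                             stringsAsFactors = FALSE,
                             fileEncoding = "UTF-8"))
  }
  cfg <- manifest$config
  config <- synthetic_config(
    seed = cfg$seed, index_year = cfg$index_year, max_age = cfg$max_age,
    child_slope = unlist(cfg$child_slope), adult_slope = unlist(cfg$adult_slope),
    noise_sd = cfg$noise_sd, bmi_sd_fraction = cfg$bmi_sd_fraction,
    n_hist_years = cfg$n_hist_years, disease_count = cfg$disease_count,
    rr_range = unlist(cfg$rr_range), pop_mean = cfg$pop_mean,
    cost_scale = cfg$cost_scale, exchange_rate = cfg$exchange_rate,
    gdp_per_capita = cfg$gdp_per_capita, wage = cfg$wage,
    wage_penalty = cfg$wage_penalty, absenteeism_loss = cfg$absenteeism_loss
  )
  bundle <- list(config = config)
  for (nm in bundle_table_names()) bundle[[nm]] <- read_one(paste0(nm, ".csv"))
  bundle$ground_truth <- list(
    trends = read_one("ground_truth_trends.csv"),
    rr = read_one("ground_truth_rr.csv")
  )
  structure(bundle, class = "input_bundle")
}
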