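# BMI trend fitting, projection, and prevalence conversion.
#
# Mean BMI in each age/sex stratum is modelled as a linear function of
# calendar year, fitted by ordinary least squares to the historical series.
# Projection is annual through age 19; in adulthood the mean is updated only
# at 5-year age grid points (20, 25, 30, ...) and held constant between them,
# reflecting the stabilisation of BMI trajectories after adolescence. A
# stratum's BMI distribution is taken as normal with SD proportional to the
# mean, so weight-category prevalences are normal tail areas above the
# cutoffs.

#' Fit a linear calendar-time trend to one stratum's mean-BMI series
#'
#' Ordinary least squares of mean BMI on calendar year. The residual SD is
#' the usual unbiased estimate, `sqrt(RSS / (n - 2))`; it is exactly zero
#' when the observations lie on a line.
#'
#' @param series Data frame with columns `year` and `mean_bmi` (additional
#'   columns are ignored), or a numeric vector of years if `values` is given.
#' @param values Optional numeric vector of mean BMI, paired with `series`
#'   as years.
#'
#' @return An object of class `trend_model`: list with `intercept` (kg/m^2
#'   at calendar year 0), `slope` (kg/m^2 per year), `residual_sd`, `n`,
#'   and `last_year` (latest observed year).
#' @export
#' @examples
#' fit_trend(data.frame(year = c(2000, 2010, 2020),
#'                      mean_bmi = c(20, 21, 22)))
fit_trend <- function(series, values = NULL) {
  if (is.null(values)) {
    assert_that(is.data.frame(series) &&
                  all(c("year", "mean_bmi") %in% names(series)),
                "`series` needs columns `year` and `mean_bmi`",
                "oaoinvest_fit_error")
    years <- series$year
    values <- series$mean_bmi
  } else {
    years <- series
  }
  keep <- is.finite(years) & is.finite(values)
  years <- years[keep]; values <- values[keep]
  n <- length(years)
  assert_that(n >= 3, "need at least 3 observations to fit a trend",
              "oaoinvest_fit_error")
  assert_that(length(unique(years)) >= 2,
              "years are all identical; trend is unidentifiable",
              "oaoinvest_fit_error")

  fit <- lm(values ~ years)
  res <- unname(fit$residuals)
  structure(
    list(
      intercept = unname(coef(fit)[1]),
      slope = unname(coef(fit)[2]),
      residual_sd = if (n > 2) sqrt(sum(res^2) / (n - 2)) else 0,
      n = n,
      last_year = max(years)
    ),
    class = "trend_model"
  )
}

#' Fit trend models for every stratum of a bundle's BMI series
#'
#' @param bmi_series The `bmi_series` table of an input bundle
#'   (`age_group`, `age_lo`, `sex`, `year`, `mean_bmi`).
#' @return A tibble with one row per (age_group, sex): `intercept`, `slope`,
#'   `residual_sd`, `last_year`.
#' @export
fit_bmi_trends <- function(bmi_series) {
  bmi_series |>
    dplyr::group_by(.data$age_group, .data$age_lo, .data$sex) |>
    dplyr::group_modify(function(df, key) {
      m <- fit_trend(df)
      tibble::tibble(intercept = m$intercept, slope = m$slope,
                     residual_sd = m$residual_sd, last_year = m$last_year)
    }) |>
    dplyr::ungroup()
}

#' Project mean BMI from a fitted trend
#'
#' Linear extrapolation of the fitted calendar-time trend. With `step`
#' set (adult projection), the trend is evaluated only at grid years
#' `anchor, anchor + step, ...` and held constant between grid points
#' (stepwise), or linearly interpolated with `method = "linear"`.
#'
#' @param model A `trend_model`.
#' @param years Calendar years to project at (must not precede the last
#'   observed year when the model was fitted to data).
#' @param step Optional grid spacing in years; `NULL` for annual projection.
#' @param anchor First grid year (required when `step` is given).
#' @param method `"hold"` (stepwise-constant, default) or `"linear"`.
#'
#' @return Numeric vector of projected mean BMI, one per year.
#' @export
project_mean_bmi <- function(model, years, step = NULL, anchor = NULL,
                             method = c("hold", "linear")) {
  method <- match.arg(method)
  assert_that(inherits(model, "trend_model"), "`model` must be a trend_model",
              "oaoinvest_fit_error")
  assert_that(length(years) > 0, "`years` must be non-empty",
              "oaoinvest_fit_error")
  if (!is.null(model$last_year)) {
    assert_that(all(years >= model$last_year),
                "projection years must not precede the fitted series",
                "oaoinvest_fit_error")
  }
  line <- function(y) model$intercept + model$slope * y
  if (is.null(step)) return(line(years))
  assert_that(is_scalar_number(step) && step > 0, "`step` must be positive",
              "oaoinvest_fit_error")
  assert_that(!is.null(anchor), "`anchor` grid year required with `step`",
              "oaoinvest_fit_error")
  lower <- anchor + step * floor((years - anchor) / step)
  if (method == "hold") return(line(lower))
  frac <- (years - lower) / step
  (1 - frac) * line(lower) + frac * line(lower + step)
}

#' Weight-category prevalences from a normal BMI distribution
#'
#' Treats BMI within a stratum as Normal(mean, sd) and returns the tail
#' areas: obese above the obese cutoff, overweight between the cutoffs,
#' normal weight the remainder. The three prevalences sum to one exactly.
#'
#' @param mean,sd Mean and standard deviation of BMI, kg/m^2 (`sd > 0`).
#'   Vectors are accepted and recycled against the cutoffs.
#' @param cutoffs Either a numeric vector `c(overweight =, obese =)` or a
#'   list with vectors `overweight` and `obese` (as from [cutoffs_for()]).
#'
#' @return A tibble with columns `normal`, `overweight`, `obese`.
#' @export
#' @examples
#' prevalence_from_mean(24, 3, c(overweight = 25, obese = 30))
prevalence_from_mean <- function(mean, sd, cutoffs) {
  assert_that(all(sd > 0), "`sd` must be positive", "oaoinvest_fit_error")
  if (!is.list(cutoffs)) {
    assert_that(all(c("overweight", "obese") %in% names(cutoffs)),
                "`cutoffs` needs overweight and obese values",
                "oaoinvest_fit_error")
    cutoffs <- list(overweight = cutoffs[["overweight"]],
                    obese = cutoffs[["obese"]])
  }
  assert_that(all(cutoffs$obese > cutoffs$overweight),
              "obese cutoff must exceed overweight cutoff",
              "oaoinvest_fit_error")
  p_above_ow <- pnorm(cutoffs$overweight, mean, sd, lower.tail = FALSE)
  p_ob <- pnorm(cutoffs$obese, mean, sd, lower.tail = FALSE)
  tibble::tibble(
    normal = 1 - p_above_ow,
    overweight = p_above_ow - p_ob,
    obese = p_ob
  )
}

#' Build the cohort-state table for the whole model horizon
#'
#' Advances every (index-year age, sex) stratum of the cohort from the index
#' year until it reaches the maximum age, projecting mean BMI (annual in
#' childhood, 5-year stepwise grid in adulthood, evaluated at the calendar
#' year the cohort attains each grid age) and converting means to
#' weight-category prevalences.
#'
#' @param bundle An `input_bundle`.
#' @param trends Optional pre-fitted output of [fit_bmi_trends()]; fitted
#'   from the bundle if `NULL`.
#' @param cutoffs A [cutoff_scheme()].
#' @param adult_method `"hold"` (stepwise between 5-year grid ages) or
#'   `"linear"` interpolation.
#'
#' @return A tibble of class `cohort_states`, one row per (cohort age at
#'   index year `age0`, sex, calendar year): `age`, `population` (stratum
#'   size at the index year), `mean_bmi`, `bmi_sd`, `prev_normal`,
#'   `prev_overweight`, `prev_obese`. Attributes `index_year`, `max_age`.
#' @export
build_cohort_states <- function(bundle, trends = NULL,
                                cutoffs = cutoff_scheme(),
                                adult_method = c("hold", "linear")) {
  adult_method <- match.arg(adult_method)
  assert_that(inherits(bundle, "input_bundle"),
              "`bundle` must be an input_bundle")
  if (is.null(trends)) trends <- fit_bmi_trends(bundle$bmi_series)
  index_year <- bundle$config$index_year
  max_age <- bundle$config$max_age
  sd_frac <- bundle$config$bmi_sd_fraction

  grid <- tidyr::expand_grid(
    age0 = as.numeric(0:19), sex = c("male", "female"),
    offset = as.numeric(0:(max_age - 1))
  )
  grid <- grid[grid$age0 + grid$offset <= max_age - 1, ]
  grid$year <- index_year + grid$offset
  grid$age <- grid$age0 + grid$offset
  grid$offset <- NULL

  pop_key <- paste(bundle$population$age, bundle$population$sex)
  grid$population <- bundle$population$population[
    match(paste(grid$age0, grid$sex), pop_key)
  ]

  # Trend lookup: children keyed by single age, adults by 5-year band.
  trend_key <- paste(trends$age_group, trends$sex)
  child <- grid$age < 20
  eval_year <- grid$year
  group <- character(nrow(grid))
  group[child] <- sprintf("%02d", grid$age[child])
  if (any(!child)) {
    grid_age <- 20 + 5 * floor((grid$age[!child] - 20) / 5)
    group[!child] <- sprintf("%d-%d", grid_age, grid_age + 4)
    # evaluate the band trend at the year the cohort attained the grid age
    eval_year[!child] <- grid$year[!child] - (grid$age[!child] - grid_age)
  }
  idx <- match(paste(group, grid$sex), trend_key)
  assert_that(!anyNA(idx), "bundle BMI series lacks some required strata")
  grid$mean_bmi <- trends$intercept[idx] + trends$slope[idx] * eval_year

  if (adult_method == "linear" && any(!child)) {
    sub <- which(!child)
    grid_age <- 20 + 5 * floor((grid$age[sub] - 20) / 5)
    next_age <- pmin(grid_age + 5, 20 + 5 * floor((max_age - 1 - 20) / 5))
    nxt_group <- sprintf("%d-%d", next_age, next_age + 4)
    idx2 <- match(paste(nxt_group, grid$sex[sub]), trend_key)
    y2 <- grid$year[sub] + (next_age - grid$age[sub])
    v2 <- trends$intercept[idx2] + trends$slope[idx2] * y2
    frac <- (grid$age[sub] - grid_age) / 5
    grid$mean_bmi[sub] <- (1 - frac) * grid$mean_bmi[sub] + frac * v2
  }

  grid$bmi_sd <- sd_frac * grid$mean_bmi
  cuts <- cutoffs_for(cutoffs, grid$age, grid$sex)
  prev <- prevalence_from_mean(grid$mean_bmi, grid$bmi_sd, cuts)
  grid$prev_normal <- prev$normal
  grid$prev_overweight <- prev$overweight
  grid$prev_obese <- prev$obese

  out <- tibble::as_tibble(grid)
  attr(out, "index_year") <- index_year
  attr(out, "max_age") <- max_age
  class(out) <- c("cohort_states", class(out))
  out
}
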