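# Deterministic Markov cohort life table.
#
# The cohort advances in annual cycles from the index year until every member
# reaches the maximum age. Each cycle, a stratum's all-cause death probability
# is the background (non-modelled) mortality plus the sum over modelled
# obesity-related causes of the baseline cause-specific rate scaled by
# (1 - PIF), where the potential impact fraction captures the shift in the
# weight-category distribution under an intervention scenario. Deaths at age
# a contribute (max_age - a) years of life lost; years lived with disability
# accrue as the cause YLD rate times person-years lived, likewise scaled by
# (1 - PIF). DALYs are YLL + YLD. Health outcomes are not discounted.

#' Construct a disease specification
#'
#' @param name Cause name.
#' @param rr Named numeric vector of relative risks by weight category
#'   (`normal`, `overweight`, `obese`); `rr["normal"]` must equal 1 and
#'   `rr["obese"] >= rr["overweight"] >= 1`.
#' @param rates Data frame with columns `age`, `sex`, `mortality`
#'   (deaths/person-year) and `yld` (YLD/person-year), all non-negative.
#'
#' @return An object of class `disease_spec`.
#' @export
disease_spec <- function(name, rr, rates) {
  assert_that(all(wt_categories() %in% names(rr)),
              "rr needs normal, overweight and obese entries",
              "oaoinvest_disease_error")
  rr <- rr[wt_categories()]
  assert_that(rr[["normal"]] == 1, "rr for normal weight must be 1",
              "oaoinvest_disease_error")
  assert_that(rr[["obese"]] >= rr[["overweight"]] &&
                rr[["overweight"]] >= 1,
              "need rr obese >= rr overweight >= 1",
              "oaoinvest_disease_error")
  assert_that(all(c("age", "sex", "mortality", "yld") %in% names(rates)),
              "rates needs age, sex, mortality, yld columns",
              "oaoinvest_disease_error")
  assert_that(all(rates$mortality >= 0) && all(rates$yld >= 0),
              "rates must be non-negative", "oaoinvest_disease_error")
  structure(list(name = name, rr = rr, rates = tibble::as_tibble(rates)),
            class = "disease_spec")
}

#' Disease specifications from an input bundle
#'
#' @param bundle An `input_bundle`.
#' @return A named list of [disease_spec()] objects.
#' @export
as_disease_specs <- function(bundle) {
  nms <- unique(bundle$disease_rr$disease)
  specs <- lapply(nms, function(d) {
    rr_rows <- bundle$disease_rr[bundle$disease_rr$disease == d, ]
    rr <- setNames(rr_rows$rr, rr_rows$category)
    rates <- bundle$disease_rates[bundle$disease_rates$disease == d,
                                  c("age", "sex", "mortality", "yld")]
    disease_spec(d, rr, rates)
  })
  setNames(specs, nms)
}

#' Potential impact fraction
#'
#' Relative change in a disease rate caused by shifting the weight-category
#' distribution from a baseline to a scenario:
#' `PIF = (sum(p * RR) - sum(p' * RR)) / sum(p * RR)`. Zero when the
#' distributions coincide or all relative risks are 1; negative when the
#' scenario distribution is worse.
#'
#' @param prev_base,prev_scen Named prevalence vectors over the same weight
#'   categories (each summing to 1).
#' @param rr Named relative-risk vector over the same categories.
#' @return A single fraction `<= 1`.
#' @export
#' @examples
#' pif(c(normal = .5, overweight = .3, obese = .2),
#'     c(normal = .6, overweight = .25, obese = .15),
#'     c(normal = 1, overweight = 1.5, obese = 2.5))
pif <- function(prev_base, prev_scen, rr) {
  assert_that(setequal(names(prev_base), names(rr)) &&
                setequal(names(prev_scen), names(rr)),
              "prevalence and relative-risk maps must share category keys",
              "oaoinvest_pif_error")
  keys <- names(rr)
  num_base <- sum(prev_base[keys] * rr[keys])
  num_scen <- sum(prev_scen[keys] * rr[keys])
  (num_base - num_scen) / num_base
}

#' Per-stratum PIF streams from baseline and scenario cohort states
#'
#' Computes, for every (cohort stratum, calendar year, disease), the PIF
#' implied by the scenario's weight-category prevalences, then applies the
#' implementation lag: a prevalence change in year y affects mortality and
#' morbidity from year `y + lag` onward.
#'
#' @param base,scen `cohort_states` tables on the same (age0, sex, year)
#'   grid.
#' @param diseases List of [disease_spec()]s.
#' @param lag Years between a prevalence change and its health effect
#'   (default 1).
#' @return A tibble (`age0`, `sex`, `year`, `disease`, `pif`).
#' @export
compute_pifs <- function(base, scen, diseases, lag = 1) {
  key_b <- paste(base$age0, base$sex, base$year)
  key_s <- paste(scen$age0, scen$sex, scen$year)
  assert_that(identical(sort(key_b), sort(key_s)),
              "baseline and scenario states must share the same grid",
              "oaoinvest_pif_error")
  idx <- match(key_b, key_s)
  out <- lapply(diseases, function(d) {
    rr <- d$rr
    num_base <- base$prev_normal * rr[["normal"]] +
      base$prev_overweight * rr[["overweight"]] +
      base$prev_obese * rr[["obese"]]
    num_scen <- scen$prev_normal[idx] * rr[["normal"]] +
      scen$prev_overweight[idx] * rr[["overweight"]] +
      scen$prev_obese[idx] * rr[["obese"]]
    raw <- (num_base - num_scen) / num_base
    df <- tibble::tibble(age0 = base$age0, sex = base$sex, year = base$year,
                         disease = d$name, pif_raw = raw)
    # lag: the PIF in force at year y is the raw PIF of year y - lag
    src <- match(paste(df$age0, df$sex, df$year - lag),
                 paste(df$age0, df$sex, df$year))
    df$pif <- ifelse(is.na(src), 0, df$pif_raw[src])
    df$pif_raw <- NULL
    df
  })
  dplyr::bind_rows(out)
}

#' Run the Markov cohort life table for one scenario
#'
#' @param states A `cohort_states` table (from [build_cohort_states()]).
#' @param diseases List of [disease_spec()]s.
#' @param mortality All-cause mortality table (`age`, `sex`, `rate`);
#'   background mortality is the residual after subtracting the modelled
#'   causes, floored at zero.
#' @param pifs Optional PIF table from [compute_pifs()]; `NULL` means all
#'   PIFs are zero (baseline scenario). PIFs greater than 1 are an error.
#' @param scenario Scenario name recorded on the ledger.
#' @param half_cycle If `TRUE`, deaths are treated as occurring mid-cycle:
#'   person-years are reduced by half a year per death and YLL by half a
#'   year. Default `FALSE` (deaths at cycle end).
#'
#' @return A `health_ledger`: tibble (`year`, `sex`, `deaths`, `yll`,
#'   `yld`, `daly`) with attributes `scenario`, `index_year`, `max_age`,
#'   and `person_time` (start-of-year survivors by stratum and year, used
#'   by the economic engine).
#' @export
run_cohort <- function(states, diseases, mortality, pifs = NULL,
                       scenario = "baseline", half_cycle = FALSE) {
  index_year <- attr(states, "index_year")
  max_age <- attr(states, "max_age")
  assert_that(!is.null(index_year) && !is.null(max_age),
              "`states` must come from build_cohort_states()",
              "oaoinvest_engine_error")
  assert_that(all(states$population >= 0), "negative populations",
              "oaoinvest_engine_error")
  if (!is.null(pifs)) {
    assert_that(all(pifs$pif <= 1 + 1e-12), "PIF greater than 1",
                "oaoinvest_engine_error")
  }

  mort_key <- paste(mortality$age, mortality$sex)
  d_names <- vapply(diseases, function(d) d$name, character(1))

  strata <- unique(states[, c("age0", "sex")])
  pieces <- vector("list", nrow(strata))
  pt <- vector("list", nrow(strata))
  for (i in seq_len(nrow(strata))) {
    a0 <- strata$age0[i]; sx <- strata$sex[i]
    rows <- states[states$age0 == a0 & states$sex == sx, ]
    rows <- rows[order(rows$year), ]
    ny <- nrow(rows)
    ages <- rows$age

    q_all <- mortality$rate[match(paste(ages, sx), mort_key)]
    assert_that(!anyNA(q_all), "mortality table lacks some age/sex cells",
                "oaoinvest_engine_error")

    q_dis <- matrix(0, ny, length(diseases))
    y_dis <- matrix(0, ny, length(diseases))
    for (j in seq_along(diseases)) {
      r <- diseases[[j]]$rates
      m <- match(paste(ages, sx), paste(r$age, r$sex))
      assert_that(!anyNA(m), "disease rates lack some age/sex cells",
                  "oaoinvest_engine_error")
      q_dis[, j] <- r$mortality[m]
      y_dis[, j] <- r$yld[m]
    }
    background <- pmax(q_all - rowSums(q_dis), 0)

    pif_m <- matrix(0, ny, length(diseases))
    if (!is.null(pifs)) {
      sub <- pifs[pifs$age0 == a0 & pifs$sex == sx, ]
      if (nrow(sub) > 0) {
        ri <- match(sub$year, rows$year)
        ci <- match(sub$disease, d_names)
        ok <- !is.na(ri) & !is.na(ci)
        pif_m[cbind(ri[ok], ci[ok])] <- sub$pif[ok]
      }
    }

    q_total <- pmin(1, background + rowSums(q_dis * (1 - pif_m)))
    alive <- rows$population[1] * cumprod(c(1, 1 - q_total))[seq_len(ny)]
    deaths <- alive * q_total
    if (half_cycle) {
      person_years <- alive - deaths / 2
      yll <- deaths * pmax(max_age - ages - 0.5, 0)
    } else {
      person_years <- alive
      yll <- deaths * (max_age - ages)
    }
    yld <- person_years * rowSums(y_dis * (1 - pif_m))

    pieces[[i]] <- tibble::tibble(year = rows$year, sex = sx,
                                  deaths = deaths, yll = yll, yld = yld)
    pt[[i]] <- tibble::tibble(age0 = a0, sex = sx, year = rows$year,
                              age = ages, alive = alive,
                              person_years = person_years)
  }

  ledger <- dplyr::bind_rows(pieces) |>
    dplyr::group_by(.data$year, .data$sex) |>
    dplyr::summarise(deaths = sum(.data$deaths), yll = sum(.data$yll),
                     yld = sum(.data$yld), .groups = "drop") |>
    dplyr::mutate(daly = .data$yll + .data$yld) |>
    dplyr::arrange(.data$year, .data$sex)

  attr(ledger, "scenario") <- scenario
  attr(ledger, "index_year") <- index_year
  attr(ledger, "max_age") <- max_age
  attr(ledger, "person_time") <- dplyr::bind_rows(pt)
  class(ledger) <- c("health_ledger", class(ledger))
  ledger
}

#' DALYs (and deaths, YLL, YLD) averted by a scenario
#'
#' Elementwise baseline minus scenario on the shared (year, sex) grid; the
#' DALY difference equals the YLL difference plus the YLD difference by
#' construction.
#'
#' @param base,scen `health_ledger`s over the same cohort and horizon.
#' @return A tibble (`year`, `sex`, `deaths`, `yll`, `yld`, `daly`) of
#'   averted quantities (positive = scenario better).
#' @export
dalys_averted <- function(base, scen) {
  assert_that(inherits(base, "health_ledger") &&
                inherits(scen, "health_ledger"),
              "inputs must be health ledgers", "oaoinvest_engine_error")
  kb <- paste(base$year, base$sex); ks <- paste(scen$year, scen$sex)
  assert_that(identical(kb, ks),
              "ledgers cover different horizons or strata",
              "oaoinvest_engine_error")
  tibble::tibble(
    year = base$year, sex = base$sex,
    deaths = base$deaths - scen$deaths,
    yll = base$yll - scen$yll,
    yld = base$yld - scen$yld,
    daly = base$daly - scen$daly
  )
}
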