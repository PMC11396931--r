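# Growth reference and weight-status cutoffs.
#
# Child/adolescent overweight and obesity are defined by z-scores (+1 SD and
# +2 SD) against an age- and sex-specific BMI reference; adults by the fixed
# 25 and 30 kg/m^2 thresholds. The packaged reference is SYNTHETIC: a smooth
# curve with the qualitative shape of a growth reference (infant peak,
# adiposity rebound near age 5, rise through adolescence). Users with access
# to a real reference can supply it in the same schema (age, sex, median, sd).

# Vectorised synthetic reference median/SD by age (years) and sex.
growth_reference_values <- function(age, sex) {
  med <- 15.3 + 0.9 * exp(-((age - 1) / 2)^2) + 0.034 * pmax(0, age - 5)^2
  med <- med - ifelse(sex == "female", 0.2, 0)
  list(median = med, sd = 0.9 + 0.075 * age)
}

#' Synthetic BMI growth-reference table
#'
#' A stand-in reference of median BMI and its standard deviation by single
#' year of age (0-19) and sex, used to place the +1 SD (overweight) and
#' +2 SD (obese) child cutoffs. Synthetic: shaped like a growth reference
#' but not derived from measured children.
#'
#' @return A tibble with columns `age`, `sex`, `median`, `sd`.
#' @export
synthetic_growth_reference <- function() {
  grid <- tidyr::expand_grid(age = as.numeric(0:19),
                             sex = c("male", "female"))
  vals <- growth_reference_values(grid$age, grid$sex)
  tibble::tibble(age = grid$age, sex = grid$sex,
                 median = vals$median, sd = vals$sd)
}

#' Weight-status cutoff scheme
#'
#' Bundles the adult BMI thresholds with the child z-score rule and the
#' growth-reference table it is applied against. The obese cutoff must lie
#' strictly above the overweight cutoff in every age/sex stratum.
#'
#' @param adult_overweight,adult_obese Adult BMI thresholds, kg/m^2.
#' @param child_z_overweight,child_z_obese Child cutoffs as z-scores above
#'   the reference median.
#' @param reference Growth-reference table (`age`, `sex`, `median`, `sd`);
#'   defaults to [synthetic_growth_reference()].
#'
#' @return An object of class `cutoff_scheme`.
#' @export
cutoff_scheme <- function(adult_overweight = 25, adult_obese = 30,
                          child_z_overweight = 1, child_z_obese = 2,
                          reference = synthetic_growth_reference()) {
  assert_that(adult_obese > adult_overweight,
              "adult obese cutoff must exceed the overweight cutoff")
  assert_that(child_z_obese > child_z_overweight,
              "child obese z-score must exceed the overweight z-score")
  assert_that(all(c("age", "sex", "median", "sd") %in% names(reference)),
              "reference needs columns age, sex, median, sd")
  assert_that(all(reference$sd > 0), "reference SDs must be positive")
  structure(
    list(adult_overweight = adult_overweight, adult_obese = adult_obese,
         child_z_overweight = child_z_overweight,
         child_z_obese = child_z_obese,
         reference = tibble::as_tibble(reference)),
    class = "cutoff_scheme"
  )
}

#' BMI cutoffs for given ages and sexes
#'
#' @param scheme A [cutoff_scheme()].
#' @param age,sex Vectors (recycled to common length).
#' @return A list with numeric vectors `overweight` and `obese` (kg/m^2).
#' @export
cutoffs_for <- function(scheme, age, sex) {
  n <- max(length(age), length(sex))
  age <- rep_len(age, n); sex <- rep_len(sex, n)
  ow <- rep(scheme$adult_overweight, n)
  ob <- rep(scheme$adult_obese, n)
  child <- age < 20
  if (any(child)) {
    key <- paste(scheme$reference$age, scheme$reference$sex)
    idx <- match(paste(age[child], sex[child]), key)
    assert_that(!anyNA(idx),
                "growth reference lacks some child age/sex strata")
    m <- scheme$reference$median[idx]
    s <- scheme$reference$sd[idx]
    ow[child] <- m + scheme$child_z_overweight * s
    ob[child] <- m + scheme$child_z_obese * s
  }
  assert_that(all(ob > ow), "obese cutoff must exceed overweight cutoff")
  list(overweight = ow, obese = ob)
}
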