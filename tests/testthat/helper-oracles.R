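# Independent oracles and toy fixtures. These reimplement the quantities
# under test from first principles (closed forms, explicit enumeration) and
# must stay independent of the package's own code paths.

# Closed-form ordinary least squares via the normal equations.
ols_oracle <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y); sxy <- sum(x * y); sxx <- sum(x * x)
  slope <- (n * sxy - sx * sy) / (n * sxx - sx^2)
  intercept <- sy / n - slope * sx / n
  resid <- y - intercept - slope * x
  list(intercept = intercept, slope = slope,
       residual_sd = sqrt(sum(resid^2) / (n - 2)))
}

# Direct weighted-sum evaluation of the potential impact fraction.
pif_oracle <- function(prev_base, prev_scen, rr) {
  num <- 0; den <- 0
  for (k in names(rr)) {
    den <- den + prev_base[[k]] * rr[[k]]
    num <- num + prev_scen[[k]] * rr[[k]]
  }
  (den - num) / den
}

# Normal tail areas by numerical quadrature of the density.
tail_area_oracle <- function(mean, sd, lower, upper) {
  stats::integrate(function(x) stats::dnorm(x, mean, sd), lower, upper,
                   rel.tol = 1e-12)$value
}

# Exhaustive year-by-year enumeration of a small cohort stratum.
# all_cause / q_dis / yld_dis are vectors/matrices indexed by age 0..max_age-1
# (columns = diseases); pif_m is a (years x diseases) matrix aligned with the
# years the stratum lives through.
cohort_oracle <- function(pop0, age0, max_age, all_cause, q_dis, yld_dis,
                          pif_m) {
  alive <- pop0
  years <- seq_len(max_age - age0)
  out <- data.frame(t = years, age = age0 + years - 1, alive = NA_real_,
                    deaths = NA_real_, yll = NA_real_, yld = NA_real_)
  for (i in years) {
    age <- age0 + i - 1
    ai <- age + 1  # 1-based index
    qd_base <- sum(q_dis[ai, ])
    background <- max(all_cause[ai] - qd_base, 0)
    qd_eff <- 0; yld_rate <- 0
    for (j in seq_len(ncol(q_dis))) {
      qd_eff <- qd_eff + q_dis[ai, j] * (1 - pif_m[i, j])
      yld_rate <- yld_rate + yld_dis[ai, j] * (1 - pif_m[i, j])
    }
    q <- min(1, background + qd_eff)
    deaths <- alive * q
    out$alive[i] <- alive
    out$deaths[i] <- deaths
    out$yll[i] <- deaths * (max_age - age)
    out$yld[i] <- alive * yld_rate
    alive <- alive - deaths
  }
  out
}

# Hand-built cohort-state table for toy engine tests: one row per
# (age0, sex, year) with explicit prevalences.
make_toy_states <- function(df, index_year, max_age) {
  out <- tibble::as_tibble(df)
  attr(out, "index_year") <- index_year
  attr(out, "max_age") <- max_age
  class(out) <- c("cohort_states", class(out))
  out
}

# A uniform toy stratum: baseline prevalence identical at every age.
toy_states_single <- function(age0 = 88, pop = 1, index_year = 2025,
                              max_age = 90, sex = "male",
                              prev = c(normal = 1, overweight = 0,
                                       obese = 0)) {
  years <- index_year + 0:(max_age - 1 - age0)
  make_toy_states(
    tibble::tibble(
      age0 = age0, sex = sex, year = years, age = age0 + years - index_year,
      population = pop, mean_bmi = 22, bmi_sd = 2,
      prev_normal = prev[["normal"]],
      prev_overweight = prev[["overweight"]],
      prev_obese = prev[["obese"]]
    ),
    index_year, max_age
  )
}

# Flat-rate disease over all ages/sexes.
toy_disease <- function(name, rr_ow, rr_ob, mortality, yld = 0,
                        max_age = 90) {
  grid <- expand.grid(age = as.numeric(0:(max_age - 1)),
                      sex = c("male", "female"),
                      stringsAsFactors = FALSE)
  disease_spec(name,
               c(normal = 1, overweight = rr_ow, obese = rr_ob),
               tibble::tibble(age = grid$age, sex = grid$sex,
                              mortality = mortality, yld = yld))
}

toy_mortality <- function(rate, max_age = 90) {
  grid <- expand.grid(age = as.numeric(0:(max_age - 1)),
                      sex = c("male", "female"),
                      stringsAsFactors = FALSE)
  tibble::tibble(age = grid$age, sex = grid$sex, rate = rate)
}

# Small shared synthetic setup for pipeline-level tests (cached per session).
small_setup <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      bundle <- generate_bundle(synthetic_config(seed = 42))
      states <- build_cohort_states(bundle)
      cache <<- list(bundle = bundle, states = states,
                     diseases = as_disease_specs(bundle))
    }
    cache
  }
})
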