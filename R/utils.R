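# Internal helpers shared across modules.

#' Run code with a locally seeded RNG, restoring the caller's RNG state
#' @noRd
with_local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  force(code)
}

#' Stop with a consistent error class
#' @noRd
abort_oao <- function(msg, class = "oaoinvest_error") {
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

assert_that <- function(cond, msg, class = "oaoinvest_error") {
  if (!isTRUE(cond)) abort_oao(msg, class)
  invisible(TRUE)
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

# Weight-status categories, in fixed order used throughout.
wt_categories <- function() c("normal", "overweight", "obese")
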