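#' Evaluate an expression under a temporary RNG seed
#'
#' Saves the caller-visible RNG state, seeds it with `seed`, evaluates
#' `code`, and restores the previous state on exit, so library internals
#' never perturb user-level randomness.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  code
}

# Stable 31-bit hash of a string; used to split one cohort-level seed into
# independent per-patient streams so adding patients never perturbs the
# earlier ones.
hash_id <- function(id) {
  codes <- utf8ToInt(id)
  h <- 0
  for (k in codes) h <- (h * 131 + k) %% 2147483647
  as.integer(h)
}

patient_seed <- function(cohort_seed, patient_id) {
  as.integer((as.numeric(cohort_seed) + hash_id(patient_id)) %% 2147483647)
}

stop2 <- function(fmt, ..., class) {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "gliomafuse_error")))
}

check_positive <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0))
    stop2("'%s' must be strictly positive and finite", name,
          class = "validation_error")
  invisible(x)
}

check_range <- function(x, name) {
  if (length(x) == 1) x <- c(x, x)
  if (length(x) != 2 || any(!is.finite(x)) || x[1] > x[2])
    stop2("'%s' must be a non-decreasing range (or a single value)", name,
          class = "validation_error")
  x
}

draw_range <- function(r, n = 1) if (r[1] == r[2]) rep(r[1], n) else runif(n, r[1], r[2])

`%||%` <- function(a, b) if (is.null(a)) b else a
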