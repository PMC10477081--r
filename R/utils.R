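# Internal helpers shared across modules.

AGES <- 0:100
SEXES <- c("female", "male")

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Convert an instantaneous rate to a per-cycle transition probability
#'
#' Uses the standard exponential conversion `p = 1 - exp(-r * t)` for an
#' annual cycle (`t = 1`), which guarantees a probability in `[0, 1)` for any
#' non-negative rate.
#'
#' @param rate Non-negative event rate per person-year (vector or matrix).
#' @param t Cycle length in years (default 1).
#' @return Per-cycle transition probability, same shape as `rate`.
#' @export
rate_to_prob <- function(rate, t = 1) {
  if (any(rate < 0, na.rm = TRUE)) stop("rates must be non-negative")
  1 - exp(-rate * t)
}

#' Convert a per-cycle probability back to an instantaneous rate
#'
#' Inverse of [rate_to_prob()]: `r = -log(1 - p)`.
#'
#' @param p Probability in `[0, 1)`.
#' @param t Cycle length in years (default 1).
#' @return Event rate per person-year.
#' @export
prob_to_rate <- function(p, t = 1) {
  if (any(p < 0 | p >= 1, na.rm = TRUE)) stop("probabilities must lie in [0, 1)")
  -log(1 - p) / t
}

# An (age x sex) matrix filled with `x`, dimnames fixed so every module agrees
# on orientation: rows are single ages 0-100, columns female/male.
age_sex_matrix <- function(x = 0) {
  matrix(x, nrow = length(AGES), ncol = length(SEXES),
         dimnames = list(age = AGES, sex = SEXES))
}

stopifnot_scalar <- function(x, name = deparse(substitute(x))) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name))
  invisible(x)
}
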