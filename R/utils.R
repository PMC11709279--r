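#' @keywords internal
"_PACKAGE"

## Condition token reserved for the blank (uniform grey) stimulus.
BLANK <- "blank"

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Minimal circular difference between two directions
#'
#' Folds the difference between two motion directions (degrees) onto
#' \code{[0, 180]}: 0 means identical preferred directions, 180 means
#' opposite directions.
#'
#' @param theta_a,theta_b directions in degrees (vectors recycle).
#' @return difference in degrees, in \code{[0, 180]}.
#' @examples
#' preferred_direction_difference(350, 10)  # 20
#' preferred_direction_difference(0, 180)   # 180
#' @export
preferred_direction_difference <- function(theta_a, theta_b) {
  abs(((theta_a - theta_b + 180) %% 360) - 180)
}

#' Classify a preferred-direction difference
#'
#' Pairs with a difference below 30 degrees have "maintained" their
#' preference, pairs above 150 degrees have "reversed" it; everything in
#' between is "other".
#'
#' @param diff_deg difference in degrees, as returned by
#'   [preferred_direction_difference()].
#' @return character vector in \code{c("maintained", "reversed", "other")}.
#' @export
classify_direction_shift <- function(diff_deg) {
  out <- rep("other", length(diff_deg))
  out[diff_deg < 30] <- "maintained"
  out[diff_deg > 150] <- "reversed"
  out
}

## error function via the normal CDF
erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1

## Run code with a private RNG stream; global .Random.seed untouched.
with_local_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

## Bootstrap standard error of the median (the error bar used for
## probe-level summaries); seeded so reports are reproducible.
boot_sem_median <- function(x, n_boot = 1000, seed = 1L) {
  x <- x[is.finite(x)]
  if (length(x) < 2) return(NA_real_)
  with_local_seed(seed, {
    meds <- vapply(seq_len(n_boot), function(i) {
      stats::median(sample(x, replace = TRUE))
    }, numeric(1))
    stats::sd(meds)
  })
}

stopf <- function(cls, fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...), class = c(cls, "lamigain_error")))
}
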