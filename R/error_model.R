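## Exact 97.5% normal quantile, fixed (rather than qnorm(0.975)) for
## bit-reproducible interval <-> sigma conversion.
.Z975 <- 1.959964

## 95% error intervals per experiment, in multiples of delta_cho_max.
## E0 is the error-free control.
.CC_ERROR_INTERVALS <- list(
  E0 = c(0, 0),
  E1 = c(-1, 1),
  E2 = c(0, 1),
  E3 = c(-1, 0),
  E4 = c(0.5, 1),
  E5 = c(-1, -0.5),
  E6 = c(0.95, 1.05),
  E7 = c(-1.05, -0.95),
  E8 = c(1, 1.5),
  E9 = c(-1.5, -1)
)

#' Experiment labels of the error-injection design
#'
#' `E0` is the error-free control; `E1` is symmetric about zero spanning the
#' full safe interval; even-numbered experiments inject underestimations
#' (positive errors, under-dosing), odd-numbered ones the mirror-image
#' overestimations.  `E6`/`E7` sit on the safe-interval boundary and `E8`/`E9`
#' beyond it.
#'
#' @return Character vector `c("E0", ..., "E9")`.
#' @export
cc_experiments <- function() names(.CC_ERROR_INTERVALS)

#' Build the carbohydrate-counting error distribution of an experiment
#'
#' Each experiment is defined by a 95% interval for the per-meal CC error,
#' expressed in multiples of the patient's personal limit
#' \eqn{\Delta CHO_{max}}.  The error is normal,
#' \eqn{\Delta CHO \sim N(\mu, \sigma^2)}, with \eqn{\mu} the interval
#' midpoint and \eqn{\sigma} the half-width divided by the 97.5% normal
#' quantile (1.959964), so that exactly 95% of the sampled errors fall inside
#' the printed interval.  Samples are deliberately untruncated: 5% of meals
#' exceed the interval by construction.
#'
#' @param experiment one of [cc_experiments()].
#' @param delta_cho_max the patient's maximum admissible CC error in grams
#'   (> 0), see [compute_delta_cho_max()].
#' @return An object of class `cc_error_spec` with fields `experiment`,
#'   `lower_mult`, `upper_mult`, `delta_cho_max`, `mu`, `sigma` (grams).
#' @examples
#' build_error_spec("E1", 13.11)
#' @export
build_error_spec <- function(experiment, delta_cho_max) {
  if (!is.character(experiment) || length(experiment) != 1L ||
      !experiment %in% names(.CC_ERROR_INTERVALS))
    stop("unknown experiment id; see cc_experiments()", call. = FALSE)
  if (!is.numeric(delta_cho_max) || length(delta_cho_max) != 1L ||
      !is.finite(delta_cho_max) || delta_cho_max <= 0)
    stop("'delta_cho_max' must be a single positive number", call. = FALSE)
  mult <- .CC_ERROR_INTERVALS[[experiment]]
  half <- (mult[2] - mult[1]) / 2
  structure(list(
    experiment    = experiment,
    lower_mult    = mult[1],
    upper_mult    = mult[2],
    delta_cho_max = delta_cho_max,
    mu            = (mult[1] + mult[2]) / 2 * delta_cho_max,
    sigma         = half * delta_cho_max / .Z975
  ), class = "cc_error_spec")
}

#' @export
print.cc_error_spec <- function(x, ...) {
  cat(sprintf(
    "CC error spec %s: 95%% interval [%g, %g] x %.2f g -> mu %.3f g, sigma %.3f g\n",
    x$experiment, x$lower_mult, x$upper_mult, x$delta_cho_max, x$mu, x$sigma))
  invisible(x)
}

#' Sample per-meal carbohydrate-counting errors
#'
#' Independent draws from the experiment's normal error law.  The control
#' (`sigma == 0`) returns exact zeros.
#'
#' @param spec a [build_error_spec()] object.
#' @param n number of meals (>= 1).
#' @param seed optional integer seed applied via [set.seed()] before drawing.
#' @return Numeric vector of `n` errors in grams.
#' @export
sample_errors <- function(spec, n, seed = NULL) {
  if (!inherits(spec, "cc_error_spec"))
    stop("'spec' must be a cc_error_spec object", call. = FALSE)
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n))
    stop("'n' must be a positive integer", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  if (spec$sigma == 0) rep(spec$mu, n) else rnorm(n, spec$mu, spec$sigma)
}

#' Probability that a counting error falls outside the safe interval
#'
#' Closed-form mass of the experiment's error law outside
#' \eqn{[-\Delta CHO_{max}, \Delta CHO_{max}]}:
#' \eqn{1 - [\Phi((\Delta-\mu)/\sigma) - \Phi((-\Delta-\mu)/\sigma)]}.
#' For boundary-centered experiments (E6/E7) this is 0.5; for the
#' beyond-limit experiments (E8/E9) it is 0.975; for E1 it is 0.05 by
#' construction of the 95% interval.
#'
#' @param spec a [build_error_spec()] object.
#' @param delta_cho_max safe-interval half width in grams; defaults to the
#'   value the spec was built with.
#' @return A probability in \[0, 1\].
#' @examples
#' fraction_outside_safe(build_error_spec("E8", 10))  # 0.975
#' @export
fraction_outside_safe <- function(spec, delta_cho_max = spec$delta_cho_max) {
  if (!inherits(spec, "cc_error_spec"))
    stop("'spec' must be a cc_error_spec object", call. = FALSE)
  if (!is.numeric(delta_cho_max) || length(delta_cho_max) != 1L ||
      !is.finite(delta_cho_max) || delta_cho_max <= 0)
    stop("'delta_cho_max' must be a single positive number", call. = FALSE)
  if (spec$sigma == 0)            # point mass at mu
    return(if (abs(spec$mu) <= delta_cho_max) 0 else 1)
  1 - (pnorm((delta_cho_max - spec$mu) / spec$sigma) -
         pnorm((-delta_cho_max - spec$mu) / spec$sigma))
}
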