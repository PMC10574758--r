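#' Glycemic threshold set
#'
#' The three blood-glucose anchors used by the bolus calculator and the safe
#' CC-error limit: the hypoglycemia threshold `g_low`, the dosing target
#' `g_target`, and the hyperglycemia threshold `g_high`, all in mg/dL.  The
#' defaults (70, 100, 180) follow the consensus in-range definition.
#'
#' @param g_low,g_target,g_high glucose concentrations in mg/dL; must satisfy
#'   `0 < g_low < g_target < g_high`.
#' @return An object of class `glucose_thresholds`.
#' @examples
#' glucose_thresholds()
#' @export
glucose_thresholds <- function(g_low = 70, g_target = 100, g_high = 180) {
  vals <- list(g_low = g_low, g_target = g_target, g_high = g_high)
  for (nm in names(vals)) {
    v <- vals[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop(sprintf("'%s' must be a single positive finite number", nm),
           call. = FALSE)
  }
  if (!(g_low < g_target && g_target < g_high))
    stop("thresholds must satisfy g_low < g_target < g_high", call. = FALSE)
  structure(vals, class = "glucose_thresholds")
}

#' @export
print.glucose_thresholds <- function(x, ...) {
  cat(sprintf("Glucose thresholds (mg/dL): low %g | target %g | high %g\n",
              x$g_low, x$g_target, x$g_high))
  invisible(x)
}

#' Insulin therapy parameters
#'
#' @param icr insulin-to-carbohydrate ratio, grams of carbohydrate covered by
#'   one unit of insulin (g/U).
#' @param isf insulin sensitivity factor, blood-glucose drop produced by one
#'   unit of insulin (mg/dL/U).
#' @return An object of class `therapy_params`.
#' @examples
#' therapy_params(icr = 15.9, isf = 42.2)
#' @export
therapy_params <- function(icr, isf) {
  for (nm in c("icr", "isf")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop(sprintf("'%s' must be a single positive finite number", nm),
           call. = FALSE)
  }
  structure(list(icr = icr, isf = isf), class = "therapy_params")
}

#' @export
print.therapy_params <- function(x, ...) {
  cat(sprintf("Therapy: ICR %.2f g/U, ISF %.2f mg/dL/U\n", x$icr, x$isf))
  invisible(x)
}

#' Personalized maximum admissible carbohydrate-counting error
#'
#' The largest absolute error (in grams) a patient can make when counting the
#' carbohydrates of a meal while the resulting mis-dosed bolus still keeps
#' post-prandial glucose inside the target range:
#' \deqn{\Delta CHO_{max} = \frac{ICR}{ISF}\,
#'   \min(G_H - G_T,\; G_T - G_L).}
#' A bolus error of \eqn{\Delta CHO/ICR} units shifts steady post-prandial
#' glucose by \eqn{(\Delta CHO/ICR)\cdot ISF} mg/dL, so the admissible error
#' is the glycemic headroom scaled by ICR/ISF.
#'
#' @param therapy a [therapy_params()] object.
#' @param thresholds a [glucose_thresholds()] object.
#' @return The maximum admissible CC error in grams (strictly positive).
#' @examples
#' compute_delta_cho_max(therapy_params(15.9, 42.2))  # adult-mean subject
#' @export
compute_delta_cho_max <- function(therapy, thresholds = glucose_thresholds()) {
  if (!inherits(therapy, "therapy_params"))
    stop("'therapy' must be a therapy_params object", call. = FALSE)
  if (!inherits(thresholds, "glucose_thresholds"))
    stop("'thresholds' must be a glucose_thresholds object", call. = FALSE)
  therapy$icr / therapy$isf * .glycemic_headroom(thresholds)
}

.glycemic_headroom <- function(thresholds) {
  min(thresholds$g_high - thresholds$g_target,
      thresholds$g_target - thresholds$g_low)
}

## vectorized core used by the cohort generator (no object overhead)
.delta_cho_max <- function(icr, isf, thresholds = glucose_thresholds()) {
  icr / isf * .glycemic_headroom(thresholds)
}

#' Prandial insulin bolus
#'
#' Standard bolus-calculator formula: carbohydrate coverage plus a correction
#' toward the glucose target, minus insulin still on board, clamped at zero
#' (insulin cannot be removed once a negative raw dose is suggested).
#'
#' @param cho_estimated estimated meal carbohydrates in grams (>= 0); may be a
#'   vector.
#' @param g_preprandial pre-meal blood glucose in mg/dL (> 0); may be a vector.
#' @param therapy a [therapy_params()] object.
#' @param iob insulin on board in U (>= 0); defaults to 0, matching a meal
#'   plan spaced widely enough that previous boluses have decayed.
#' @param thresholds a [glucose_thresholds()] object; only `g_target` enters.
#' @return Bolus dose(s) in U, never negative.  Doses are real-valued; no
#'   pen/pump step rounding is applied.
#' @examples
#' compute_bolus(45, 100, therapy_params(15, 50))  # 3 U, no correction
#' @export
compute_bolus <- function(cho_estimated, g_preprandial, therapy, iob = 0,
                          thresholds = glucose_thresholds()) {
  if (!inherits(therapy, "therapy_params"))
    stop("'therapy' must be a therapy_params object", call. = FALSE)
  if (!inherits(thresholds, "glucose_thresholds"))
    stop("'thresholds' must be a glucose_thresholds object", call. = FALSE)
  if (any(!is.finite(cho_estimated)) || any(cho_estimated < 0))
    stop("'cho_estimated' must be finite and >= 0", call. = FALSE)
  if (any(!is.finite(g_preprandial)) || any(g_preprandial <= 0))
    stop("'g_preprandial' must be finite and > 0", call. = FALSE)
  if (any(!is.finite(iob)) || any(iob < 0))
    stop("'iob' must be finite and >= 0", call. = FALSE)
  raw <- cho_estimated / therapy$icr +
    (g_preprandial - thresholds$g_target) / therapy$isf - iob
  pmax(0, raw)
}

#' Error-corrupted carbohydrate estimate
#'
#' Applies a counting error to the true meal content:
#' `CHO = max(0, CHO_true - delta_cho)`.  A positive `delta_cho` is an
#' underestimation (the patient counts fewer grams than eaten), a negative
#' one an overestimation.  The estimate is clamped at 0 g because a large
#' underestimation on a small meal cannot produce negative grams.
#'
#' @param cho_true true meal carbohydrates in grams (>= 0); vectorized.
#' @param delta_cho counting error(s) in grams, any sign; vectorized.
#' @return Estimated carbohydrates in grams.
#' @examples
#' estimate_cho(30, 13.11)   # underestimated meal
#' estimate_cho(30, -13.11)  # overestimated meal
#' @export
estimate_cho <- function(cho_true, delta_cho) {
  if (any(!is.finite(cho_true)) || any(cho_true < 0))
    stop("'cho_true' must be finite and >= 0", call. = FALSE)
  if (any(!is.finite(delta_cho)))
    stop("'delta_cho' must be finite", call. = FALSE)
  pmax(0, cho_true - delta_cho)
}
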