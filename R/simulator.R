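#' Metabolic model parameters
#'
#' Parameter set of the minimal glucose-insulin model used as an open
#' stand-in for a full-scale virtual patient simulator.  Glucose follows
#' \deqn{dG/dt = -p_1 (G - G_b) - s_i X + Ra(t)/V_g,}
#' with remote insulin action \eqn{dX/dt = p_2 ((I_{pl} - I_b) - X)},
#' two-compartment subcutaneous insulin kinetics (depot time constant
#' `tau_i`, clearance `i_clear`) and two-compartment gut absorption (time
#' constant `tau_m`, bioavailable fraction `bioavail`).  Insulin action is
#' additive in glucose, so the model's dose response is linear and the
#' clinical ISF (mg/dL drop per U) is a well-defined constant -- the same
#' linearity assumption that underlies the bolus-calculator arithmetic.
#'
#' `si` and `v_g` are the two free per-patient parameters fixed by
#' [calibrate_patient()]; the remaining kinetics form a shared template.
#'
#' @param p1 glucose effectiveness, 1/min (return toward `g_b` independent of
#'   insulin).
#' @param si insulin sensitivity gain, mg/dL per min per U of remote action.
#' @param p2 remote insulin action rate, 1/min.
#' @param g_b basal (fasting) glucose under the patient's basal insulin,
#'   mg/dL.
#' @param v_g glucose distribution volume, dL.
#' @param tau_i subcutaneous insulin absorption time constant, min.
#' @param tau_m meal absorption time constant, min.
#' @param bioavail fraction of meal carbohydrate reaching plasma, in (0, 1].
#' @param i_clear insulin clearance rate, 1/min.
#' @param i_b circulating insulin mass sustained by the basal infusion, U.
#' @return An object of class `metabolic_params`.
#' @examples
#' metabolic_params()
#' @export
metabolic_params <- function(p1 = 0.004, si = 2, p2 = 0.04, g_b = 100,
                             v_g = 160, tau_i = 25, tau_m = 40,
                             bioavail = 0.9, i_clear = 0.04, i_b = 0.42) {
  vals <- list(p1 = p1, si = si, p2 = p2, g_b = g_b, v_g = v_g,
               tau_i = tau_i, tau_m = tau_m, bioavail = bioavail,
               i_clear = i_clear, i_b = i_b)
  for (nm in names(vals)) {
    v <- vals[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop(sprintf("'%s' must be a single positive finite number", nm),
           call. = FALSE)
  }
  if (bioavail > 1)
    stop("'bioavail' must be in (0, 1]", call. = FALSE)
  structure(vals, class = "metabolic_params")
}

#' @export
print.metabolic_params <- function(x, ...) {
  cat("Minimal metabolic model parameters:\n")
  cat(sprintf("  glucose:  p1 %.4g /min, g_b %.4g mg/dL, v_g %.4g dL\n",
              x$p1, x$g_b, x$v_g))
  cat(sprintf("  insulin:  si %.4g mg/dL/min/U, p2 %.4g /min, tau_i %.4g min, i_clear %.4g /min, i_b %.4g U\n",
              x$si, x$p2, x$tau_i, x$i_clear, x$i_b))
  cat(sprintf("  meal:     tau_m %.4g min, bioavail %.4g\n",
              x$tau_m, x$bioavail))
  invisible(x)
}

.CGM_DT <- 5  # minutes between samples

## equilibrium state under a given basal infusion (U/h), glucose pinned at g0
.cc_state0 <- function(params, basal, g0 = params$g_b) {
  u <- basal / 60
  c(G = g0, X = u / params$i_clear - params$i_b,
    Isc1 = u * params$tau_i, Isc2 = u * params$tau_i,
    Ipl = u / params$i_clear, Q1 = 0, Q2 = 0)
}

## One solver call.  events: matrix with columns (time, a, b); mode 0 applies
## (a mg -> gut, b U -> sc depot) verbatim, mode 1 treats (a, b) as
## (grams true, counting error) and computes the bolus from simulated G.
## Events at t <= times[1] must be folded into y0 by the caller.
.cc_run <- function(y0, times, params, basal, mode = 0, events = NULL,
                    icr = 1, isf = 1, g_target = 100, iob = 0) {
  if (is.null(events)) events <- matrix(numeric(0), ncol = 3)
  ev <- events[events[, 1] > times[1] + 1e-9, , drop = FALSE]
  par <- c(params$p1, params$si, params$p2, params$g_b, params$v_g,
           params$tau_i, params$tau_m, params$bioavail, params$i_clear,
           params$i_b, basal / 60, mode, icr, isf, g_target, iob,
           nrow(ev), as.numeric(t(ev)))
  .Call("cc_set_inputs", as.double(par), PACKAGE = "carbsafe")
  evlist <- if (nrow(ev)) list(func = "cc_event", time = ev[, 1]) else NULL
  out <- deSolve::lsoda(y0, times, func = "cc_derivs", parms = NULL,
                        dllname = "carbsafe", initfunc = NULL,
                        events = evlist, rtol = 1e-8, atol = 1e-6,
                        maxsteps = 10000)
  if (attr(out, "istate")[1] < 0 || any(!is.finite(out[, "G"])))
    stop("metabolic model integration failed (istate ",
         attr(out, "istate")[1], ")", call. = FALSE)
  out
}

#' Simulate the glucose response to a basal-bolus regimen
#'
#' Integrates the minimal metabolic model under a constant basal infusion
#' with impulsive meals and insulin boluses, and samples plasma glucose on
#' the 5-minute CGM grid.  The run starts from the equilibrium state implied
#' by `basal` with glucose at `g0`; sampling is noise-free, so the returned
#' trace is the CGM signal of an ideal sensor.
#'
#' @param params a [metabolic_params()] object.
#' @param basal basal insulin infusion, U/h.
#' @param meals `NULL` or a data frame with columns `time` (min, multiples of
#'   5 within the horizon) and `grams`.
#' @param boluses `NULL` or a data frame with columns `time` (min) and
#'   `units`.
#' @param horizon simulation length in minutes; must be a positive multiple
#'   of 5.
#' @param g0 initial glucose, mg/dL.
#' @param check_positive error if simulated glucose becomes non-positive
#'   (a sign of an uncalibrated or overdosed configuration).  Calibration
#'   probes disable this, since a linear probe may transiently leave the
#'   physiologic range.
#' @param full_state return all model states instead of glucose only.
#' @return An object of class `glucose_trace`: a data frame with `t_min`
#'   (0, 5, ..., horizon - 5) and `glucose_mgdl`, `horizon / 5` rows (288 per
#'   simulated day).  With `full_state = TRUE`, additional columns `X`,
#'   `Isc1`, `Isc2`, `Ipl`, `Q1`, `Q2` and the meal appearance rate
#'   `ra_mg_min`.
#' @examples
#' p <- metabolic_params()
#' tr <- simulate_response(p, basal = p$i_b * p$i_clear * 60, horizon = 1440)
#' range(tr$glucose_mgdl)  # flat at g_b: equilibrium
#' @export
simulate_response <- function(params, basal, meals = NULL, boluses = NULL,
                              horizon, g0 = params$g_b,
                              check_positive = TRUE, full_state = FALSE) {
  if (!inherits(params, "metabolic_params"))
    stop("'params' must be a metabolic_params object", call. = FALSE)
  if (!is.numeric(basal) || length(basal) != 1L || basal < 0)
    stop("'basal' must be a single non-negative number (U/h)", call. = FALSE)
  if (!is.numeric(horizon) || length(horizon) != 1L || horizon <= 0 ||
      horizon %% .CGM_DT != 0)
    stop("'horizon' must be a positive multiple of 5 min", call. = FALSE)
  ev <- rbind(
    if (!is.null(meals) && nrow(as.data.frame(meals)))
      cbind(meals$time, params$bioavail * meals$grams * 1000, 0),
    if (!is.null(boluses) && nrow(as.data.frame(boluses)))
      cbind(boluses$time, 0, boluses$units)
  )
  if (is.null(ev)) ev <- matrix(numeric(0), ncol = 3)
  if (nrow(ev)) {
    if (any(ev[, 1] < 0) || any(ev[, 1] >= horizon))
      stop("meal/bolus times must lie in [0, horizon)", call. = FALSE)
    if (any(ev[, 1] %% .CGM_DT != 0))
      stop("meal/bolus times must fall on the 5-min grid", call. = FALSE)
  }
  y0 <- .cc_state0(params, basal, g0)
  at0 <- nrow(ev) > 0 & ev[, 1] <= 1e-9
  if (any(at0)) {
    y0["Q1"] <- y0["Q1"] + sum(ev[at0, 2])
    y0["Isc1"] <- y0["Isc1"] + sum(ev[at0, 3])
  }
  times <- seq(0, horizon, by = .CGM_DT)
  out <- .cc_run(y0, times, params, basal, mode = 0, events = ev)
  out <- out[-nrow(out), , drop = FALSE]  # half-open [0, horizon)
  g <- out[, "G"]
  if (check_positive && any(g <= 0))
    stop("simulated glucose became non-positive; the configuration is ",
         "overdosed or uncalibrated", call. = FALSE)
  tr <- data.frame(t_min = out[, "time"], glucose_mgdl = g)
  if (full_state) {
    tr <- cbind(tr, as.data.frame(out[, c("X", "Isc1", "Isc2", "Ipl",
                                          "Q1", "Q2"), drop = FALSE]))
    tr$ra_mg_min <- out[, "Q2"] / params$tau_m
  }
  class(tr) <- c("glucose_trace", "data.frame")
  tr
}

#' @export
print.glucose_trace <- function(x, ...) {
  cat(sprintf("Glucose trace: %d samples (%.1f days at 5 min), %s%.0f-%.0f mg/dL\n",
              nrow(x), nrow(x) / 288, "range ",
              min(x$glucose_mgdl), max(x$glucose_mgdl)))
  invisible(x)
}

#' @export
plot.glucose_trace <- function(x, ...) {
  plot(x$t_min / 60, x$glucose_mgdl, type = "l", xlab = "time (h)",
       ylab = "glucose (mg/dL)", ...)
  abline(h = c(70, 180), lty = 3, col = "grey40")
  invisible(x)
}

#' Measure the model's effective insulin sensitivity factor
#'
#' Administers an extra bolus at basal equilibrium and returns the maximal
#' glucose drop per unit, the model analogue of the clinical ISF.  For
#' high-ISF subjects the probe trajectory may transiently fall below the
#' physiologic range; because the model is linear in insulin action the
#' measured drop is still the per-unit sensitivity, so the positivity check
#' is disabled for this probe.
#'
#' @param params a [metabolic_params()] object.
#' @param bolus probe dose, U.
#' @param horizon observation window, min.
#' @return Maximal drop below `g_b` divided by `bolus`, mg/dL/U.
#' @export
measure_isf <- function(params, bolus = 1, horizon = 600) {
  basal <- params$i_b * params$i_clear * 60
  tr <- simulate_response(params, basal,
                          boluses = data.frame(time = 0, units = bolus),
                          horizon = horizon, check_positive = FALSE)
  (params$g_b - min(tr$glucose_mgdl)) / bolus
}

#' Measure post-meal glucose recovery under exact dosing
#'
#' Gives a meal together with its exact carbohydrate-matched bolus
#' (`grams / icr` U, no correction needed at equilibrium) and reports the
#' simulated glucose at `t_eval` minutes, the instant at which a correctly
#' dosed meal should be back near target.
#'
#' @param params a [metabolic_params()] object.
#' @param icr insulin-to-carbohydrate ratio, g/U.
#' @param grams meal size, g.
#' @param t_eval evaluation time, min (multiple of 5).
#' @return Glucose at `t_eval`, mg/dL.
#' @export
measure_meal_recovery <- function(params, icr, grams = 60, t_eval = 150) {
  basal <- params$i_b * params$i_clear * 60
  horizon <- t_eval + 50
  tr <- simulate_response(params, basal,
                          meals = data.frame(time = 0, grams = grams),
                          boluses = data.frame(time = 0, units = grams / icr),
                          horizon = horizon, check_positive = FALSE)
  tr$glucose_mgdl[match(t_eval, tr$t_min)]
}

## bounded bisection on a monotone objective; returns the root location
.bisect <- function(f, lo, hi, tol_f, maxit = 60, stage = "bisection") {
  flo <- f(lo); fhi <- f(hi)
  if (!is.finite(flo) || !is.finite(fhi) || sign(flo) == sign(fhi))
    stop(sprintf("%s: no sign change over [%g, %g] (f = %g, %g)",
                 stage, lo, hi, flo, fhi), call. = FALSE)
  for (i in seq_len(maxit)) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (abs(fm) <= tol_f) return(mid)
    if (sign(fm) == sign(flo)) { lo <- mid; flo <- fm } else hi <- mid
  }
  stop(sprintf("%s: no convergence in %d iterations (bracket [%g, %g])",
               stage, maxit, lo, hi), call. = FALSE)
}

#' Calibrate the metabolic model to a patient's therapy parameters
#'
#' Two-stage deterministic calibration so that the model honors the only
#' patient-specific quantities the dosing method uses:
#' \enumerate{
#'   \item `si` is tuned by bisection until a 1 U bolus at equilibrium
#'     produces a maximal glucose drop equal to the assigned ISF (relative
#'     tolerance 0.5%);
#'   \item `v_g` is tuned by bisection until a 60 g meal dosed with exactly
#'     `60 / ICR` U returns glucose to within 0.5 mg/dL of target at
#'     150 minutes.
#' }
#' Stage 1 is independent of `v_g` (no meal input), so the stages do not
#' interact.  Both searches are bounded and fail loudly, naming the stage.
#'
#' @param therapy a [therapy_params()] object.
#' @param template a [metabolic_params()] object supplying the shared
#'   kinetics; its `si` and `v_g` entries are overwritten.
#' @param si_bracket,vg_bracket search intervals for the two stages.
#' @return A calibrated [metabolic_params()] object.
#' @examples
#' \donttest{
#' p <- calibrate_patient(therapy_params(15.9, 42.2))
#' measure_isf(p)  # ~42.2
#' }
#' @export
calibrate_patient <- function(therapy, template = metabolic_params(),
                              si_bracket = c(1e-3, 500),
                              vg_bracket = c(2, 50000)) {
  if (!inherits(therapy, "therapy_params"))
    stop("'therapy' must be a therapy_params object", call. = FALSE)
  p <- template
  p$si <- .bisect(function(si) {
    p$si <- si
    measure_isf(p) - therapy$isf
  }, si_bracket[1], si_bracket[2], tol_f = 0.005 * therapy$isf,
  stage = "calibration stage 1 (si vs ISF)")
  p$v_g <- .bisect(function(vg) {
    p$v_g <- vg
    measure_meal_recovery(p, therapy$icr) - p$g_b
  }, vg_bracket[1], vg_bracket[2], tol_f = 0.5,
  stage = "calibration stage 2 (v_g vs meal recovery)")
  p
}

#' Basal infusion holding fasting glucose at a target
#'
#' Finds, by bisection on 48-hour meal-free simulations, the constant basal
#' rate whose equilibrium glucose equals `g_target_fasting`.  Errors when no
#' basal in \[0, 10\] U/h brackets the target (e.g. a near-zero insulin
#' sensitivity makes glucose insensitive to the infusion).
#'
#' @param params a [metabolic_params()] object.
#' @param g_target_fasting desired fasting glucose, mg/dL.
#' @param tol accepted deviation of the 48-h endpoint from target, mg/dL.
#' @return Basal rate in U/h.
#' @export
steady_state_basal <- function(params, g_target_fasting = params$g_b,
                               tol = 0.5) {
  if (!inherits(params, "metabolic_params"))
    stop("'params' must be a metabolic_params object", call. = FALSE)
  endpoint <- function(basal) {
    tr <- simulate_response(params, basal, horizon = 48 * 60,
                            check_positive = FALSE)
    tr$glucose_mgdl[nrow(tr)]
  }
  f <- function(basal) endpoint(basal) - g_target_fasting
  flo <- f(0); fhi <- f(10)
  if (!(flo > tol && fhi < -tol))
    stop("no bracketing basal in [0, 10] U/h: fasting glucose spans [",
         sprintf("%.2f, %.2f", endpoint(10), endpoint(0)),
         "] mg/dL and cannot reach the target", call. = FALSE)
  .bisect(f, 0, 10, tol_f = tol, stage = "steady-state basal search")
}
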