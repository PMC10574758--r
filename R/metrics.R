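#' Range-occupancy metrics of a glucose trace
#'
#' Computes the standard CGM consensus metrics as percentages of samples:
#' time in range (TIR, 70-180 mg/dL inclusive), time above range (TAR,
#' strictly > 180), time below range (TBR, strictly < 70), and the severe
#' tails below 50 and above 300 mg/dL.  The closed in-range interval makes
#' TIR, TAR and TBR a partition: they sum to exactly 100 for every trace.
#' Sample counting is equivalent to time weighting because the grid is
#' uniform.
#'
#' @param trace a [simulate_response()] trace, or a numeric vector of glucose
#'   values in mg/dL.
#' @param lower,upper in-range bounds, mg/dL (closed interval).
#' @param severe_low,severe_high severe hypo-/hyperglycemia cutoffs, mg/dL.
#' @return A one-row data frame of class `glycemic_outcome` with columns
#'   `tir`, `tar`, `tbr`, `pct_below_50`, `pct_above_300`, all in percent.
#' @examples
#' compute_metrics(c(60, 65, 200, 310))
#' @export
compute_metrics <- function(trace, lower = 70, upper = 180,
                            severe_low = 50, severe_high = 300) {
  g <- if (is.data.frame(trace)) trace$glucose_mgdl else trace
  if (is.null(g) || !length(g))
    stop("empty glucose trace", call. = FALSE)
  if (any(!is.finite(g)))
    stop("glucose trace contains non-finite values", call. = FALSE)
  n <- length(g)
  out <- data.frame(
    tir           = 100 * sum(g >= lower & g <= upper) / n,
    tar           = 100 * sum(g > upper) / n,
    tbr           = 100 * sum(g < lower) / n,
    pct_below_50  = 100 * sum(g < severe_low) / n,
    pct_above_300 = 100 * sum(g > severe_high) / n
  )
  class(out) <- c("glycemic_outcome", "data.frame")
  out
}

#' Total number of meals over a trial
#'
#' @param plan a daily meal plan as returned by [meal_plan()] (or any data
#'   frame with one row per daily meal; may be empty).
#' @param days number of trial days (>= 0).
#' @return `days * nrow(plan)`.
#' @examples
#' count_meals(meal_plan("adult"), 90)  # 450
#' @export
count_meals <- function(plan, days) {
  if (!is.numeric(days) || length(days) != 1L || days < 0 ||
      days != round(days))
    stop("'days' must be a non-negative integer", call. = FALSE)
  nr <- if (is.null(plan)) 0L else nrow(as.data.frame(plan))
  as.integer(nr * days)
}
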