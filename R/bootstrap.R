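#' Apply the control-arm exclusion criterion and build analysis strata
#'
#' Subjects whose error-free control (E0) time in range falls below
#' `min_tir` are excluded, so that glucose dysregulation unrelated to
#' carbohydrate counting does not contaminate the comparisons.  Two strata
#' are reported for the retained subjects: those always in range
#' (`TIR == 100`) and all retained (`TIR >= min_tir`).
#'
#' @param control_records data frame with one row per subject and columns
#'   `id` and `tir` (control-arm TIR, percent).
#' @param min_tir exclusion threshold, percent.
#' @return A list with character vectors `retained`, `excluded`, `tir100`
#'   and `tir90` (the latter named after the default threshold; it equals
#'   `retained`).
#' @export
exclude_subjects <- function(control_records, min_tir = 90) {
  stopifnot(is.data.frame(control_records),
            all(c("id", "tir") %in% names(control_records)))
  if (anyDuplicated(control_records$id))
    stop("one control record per subject expected", call. = FALSE)
  eps <- 1e-9
  keep <- control_records$tir >= min_tir - eps
  list(
    retained = control_records$id[keep],
    excluded = control_records$id[!keep],
    tir100   = control_records$id[control_records$tir >= 100 - eps],
    tir90    = control_records$id[keep]
  )
}

#' Shapiro-Wilk normality gate
#'
#' Diagnostic normality check used before the inference step.  The analysis
#' always proceeds with the nonparametric bootstrap regardless of the
#' outcome; the gate only documents whether a normal-theory interval would
#' also have been defensible.
#'
#' @param x numeric sample, at least 3 non-degenerate values.
#' @param alpha significance level of the flag.
#' @return A list with `statistic`, `p_value` and logical `normal`
#'   (`p_value > alpha`).
#' @export
shapiro_wilk_gate <- function(x, alpha = 0.05) {
  x <- as.numeric(x)
  if (length(x) < 3)
    stop("need at least 3 observations", call. = FALSE)
  if (diff(range(x)) == 0)
    stop("degenerate (constant) sample", call. = FALSE)
  sw <- shapiro.test(x)
  list(statistic = unname(sw$statistic), p_value = sw$p.value,
       normal = sw$p.value > alpha)
}

#' Paired nonparametric bootstrap for a difference of means
#'
#' Resamples the per-subject differences `d_i = experiment - control` with
#' replacement and reports the observed mean difference, the percentile
#' confidence interval of the resampled means, and a two-sided bootstrap
#' p-value by tail doubling,
#' `p = min(1, 2 min(P*(mean* <= 0), P*(mean* >= 0)))`.  The resampling unit
#' is the subject, matching the paired design.
#'
#' @param values_experiment,values_control metric values (percent), one per
#'   subject, aligned; at least 2 subjects.
#' @param n_resamples bootstrap resamples.
#' @param seed optional integer seed.
#' @param level confidence level of the percentile interval.
#' @return An object of class `cc_boot`: list with `mean_diff`, `ci_low`,
#'   `ci_high`, `p_value`, `n_subjects`, `n_resamples`, `level`, `seed`.
#' @examples
#' b <- bootstrap_paired_diff(c(95, 92, 90, 97), c(99, 98, 97, 100),
#'                            n_resamples = 2000, seed = 1)
#' b$mean_diff
#' @export
bootstrap_paired_diff <- function(values_experiment, values_control,
                                  n_resamples = 10000, seed = NULL,
                                  level = 0.95) {
  ve <- as.numeric(values_experiment)
  vc <- as.numeric(values_control)
  if (length(ve) != length(vc))
    stop("paired samples must have equal length", call. = FALSE)
  if (length(ve) < 2)
    stop("need at least 2 subjects", call. = FALSE)
  if (any(!is.finite(ve)) || any(!is.finite(vc)))
    stop("non-finite metric values", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  d <- ve - vc
  n <- length(d)
  idx <- sample.int(n, n * n_resamples, replace = TRUE)
  bm <- colMeans(matrix(d[idx], nrow = n, ncol = n_resamples))
  alpha <- (1 - level) / 2
  ci <- unname(quantile(bm, c(alpha, 1 - alpha)))
  structure(list(
    mean_diff   = mean(d),
    ci_low      = ci[1],
    ci_high     = ci[2],
    p_value     = min(1, 2 * min(mean(bm <= 0), mean(bm >= 0))),
    n_subjects  = n,
    n_resamples = n_resamples,
    level       = level,
    seed        = seed
  ), class = "cc_boot")
}

#' @export
print.cc_boot <- function(x, ...) {
  cat(sprintf(
    "Paired bootstrap: mean diff %.3f [%g%% CI %.3f, %.3f], p = %.4f (n = %d, B = %d)\n",
    x$mean_diff, 100 * x$level, x$ci_low, x$ci_high, x$p_value,
    x$n_subjects, x$n_resamples))
  invisible(x)
}
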