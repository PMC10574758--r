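## Per-subject maximum admissible CC errors (grams) for the reference
## virtual population: 10 numbered subjects plus the population-average
## subject ("Avg") in each age group.  The Avg row is a genuine 11th subject,
## not a column mean (the adult rows 1-10 average to 11.29, not 11.03).
.ROSTER_DELTA <- list(
  adult      = c(13.11, 16.02, 12.42, 11.11, 8.41, 10.42, 12.78, 7.12,
                 11.09, 10.46, 11.03),
  adolescent = c(9.90, 7.72, 12.76, 6.42, 5.50, 10.06, 16.55, 7.04,
                 7.95, 8.52, 8.63),
  child      = c(5.48, 8.03, 9.58, 5.37, 6.87, 7.40, 5.55, 5.70,
                 5.89, 10.06, 6.41)
)

## Age-group summary statistics of the therapy parameters (mean +/- sd).
.COHORT_STATS <- data.frame(
  cohort   = c("adult", "adolescent", "child"),
  icr_mean = c(15.9, 17.6, 26.5),
  icr_sd   = c(4.5, 7.0, 5.3),
  isf_mean = c(42.2, 57.1, 117.8),
  isf_sd   = c(8.0, 13.8, 27.7),
  stringsAsFactors = FALSE
)

.ROSTER_COLS <- c("id", "cohort", "icr", "isf", "delta_cho_max", "basal")
.CSV_COLS <- c("id", "cohort", "icr_g_per_U", "isf_mgdl_per_U",
               "delta_cho_max_g", "basal_U_per_h")

#' Age-group therapy parameter statistics
#'
#' Mean and standard deviation of the insulin-to-carbohydrate ratio (g/U) and
#' insulin sensitivity factor (mg/dL/U) for the adult, adolescent and child
#' virtual populations.
#'
#' @param cohort optionally restrict to one of `"adult"`, `"adolescent"`,
#'   `"child"`.
#' @return A data frame with columns `cohort`, `icr_mean`, `icr_sd`,
#'   `isf_mean`, `isf_sd`.
#' @export
cohort_stats <- function(cohort = NULL) {
  if (is.null(cohort)) return(.COHORT_STATS)
  cohort <- match.arg(cohort, .COHORT_STATS$cohort)
  .COHORT_STATS[.COHORT_STATS$cohort == cohort, , drop = FALSE]
}

#' The 33-subject reference virtual roster
#'
#' A fixed population of 11 adults, 11 adolescents and 11 children with known
#' per-subject maximum admissible CC errors.  Individual ICR/ISF pairs are
#' not published for this population, so each subject's ICR is set to its age
#' group's mean and ISF is derived as `icr * 30 / delta_cho_max`; the ICR/ISF
#' ratio -- the only per-subject quantity the downstream analysis depends on
#' -- then reproduces the tabulated `delta_cho_max` exactly under the
#' standard 70/100/180 mg/dL thresholds.
#'
#' @param template a [metabolic_params()] template supplying the basal-rate
#'   kinetics shared by all subjects.
#' @return A data frame with columns `id`, `cohort`, `icr` (g/U), `isf`
#'   (mg/dL/U), `delta_cho_max` (g) and `basal` (U/h).
#' @examples
#' r <- load_reference_roster()
#' r[r$id == "Adult#1", ]
#' @export
load_reference_roster <- function(template = metabolic_params()) {
  headroom <- 30  # min(180 - 100, 100 - 70)
  out <- do.call(rbind, lapply(names(.ROSTER_DELTA), function(co) {
    d <- .ROSTER_DELTA[[co]]
    icr <- .COHORT_STATS$icr_mean[.COHORT_STATS$cohort == co]
    lab <- paste0(toupper(substring(co, 1, 1)), substring(co, 2))
    data.frame(
      id            = paste0(lab, "#", c(seq_len(10), "Avg")),
      cohort        = co,
      icr           = icr,
      isf           = icr * headroom / d,
      delta_cho_max = d,
      basal         = template$i_b * template$i_clear * 60,
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  out
}

#' @rdname load_reference_roster
#' @export
reference_roster <- load_reference_roster

#' Summary statistics of a roster's safe CC-error limits
#'
#' @param roster a roster data frame (see [load_reference_roster()]).
#' @return A list with `mean`, `sd` (sample sd, `NA` for a single subject),
#'   `max` and `min` of `delta_cho_max` in grams, plus the subject count `n`.
#' @examples
#' summarize_roster(load_reference_roster())
#' @export
summarize_roster <- function(roster) {
  d <- roster$delta_cho_max
  if (is.null(d) || !length(d))
    stop("'roster' must be a non-empty roster data frame", call. = FALSE)
  list(mean = mean(d), sd = if (length(d) > 1) sd(d) else NA_real_,
       max = max(d), min = min(d), n = length(d))
}

#' Generate a synthetic virtual cohort
#'
#' Draws ICR and ISF independently from normal laws with the age group's
#' mean/sd, rejection-resampled to the physically plausible band
#' `[mean - 3 sd, mean + 3 sd]` intersected with the strictly positive axis,
#' then derives each subject's `delta_cho_max` under the standard thresholds.
#' The independence of the two draws is a simplification: no ICR-ISF
#' correlation is published for the reference population.
#'
#' @param cohort `"adult"`, `"adolescent"` or `"child"`.
#' @param n number of subjects (>= 1).
#' @param seed optional integer seed for reproducibility.
#' @param stats a one-row data frame as returned by `cohort_stats(cohort)`;
#'   override to generate from custom population statistics.
#' @param template a [metabolic_params()] template (basal kinetics).
#' @return A roster data frame with the same columns as
#'   [load_reference_roster()].
#' @examples
#' generate_cohort("adult", 5, seed = 1)
#' @export
generate_cohort <- function(cohort = c("adult", "adolescent", "child"), n,
                            seed = NULL, stats = NULL,
                            template = metabolic_params()) {
  cohort <- match.arg(cohort)
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n))
    stop("'n' must be a positive integer", call. = FALSE)
  if (is.null(stats)) stats <- cohort_stats(cohort)
  stopifnot(all(c("icr_mean", "icr_sd", "isf_mean", "isf_sd") %in%
                  names(stats)))
  if (!is.null(seed)) set.seed(seed)
  icr <- .rnorm_trunc(n, stats$icr_mean, stats$icr_sd)
  isf <- .rnorm_trunc(n, stats$isf_mean, stats$isf_sd)
  data.frame(
    id            = sprintf("%s#g%d", cohort, seq_len(n)),
    cohort        = cohort,
    icr           = icr,
    isf           = isf,
    delta_cho_max = .delta_cho_max(icr, isf),
    basal         = template$i_b * template$i_clear * 60,
    stringsAsFactors = FALSE
  )
}

## truncated normal by rejection: within mean +/- 3 sd and > 0
.rnorm_trunc <- function(n, mean, sd) {
  lo <- max(mean - 3 * sd, .Machine$double.eps)
  hi <- mean + 3 * sd
  if (lo >= hi) stop("degenerate truncation bounds", call. = FALSE)
  out <- numeric(0)
  while (length(out) < n) {
    x <- rnorm(n, mean, sd)
    out <- c(out, x[x >= lo & x <= hi])
  }
  out[seq_len(n)]
}

#' Read and write rosters as CSV
#'
#' The on-disk format carries explicit units in the column names:
#' `id, cohort, icr_g_per_U, isf_mgdl_per_U, delta_cho_max_g, basal_U_per_h`.
#'
#' @param roster a roster data frame.
#' @param path file path.
#' @return `read_roster()` returns a roster data frame;
#'   `write_roster()` returns `path` invisibly.
#' @export
write_roster <- function(roster, path) {
  stopifnot(all(.ROSTER_COLS %in% names(roster)))
  out <- roster[, .ROSTER_COLS]
  names(out) <- .CSV_COLS
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_roster
#' @export
read_roster <- function(path) {
  raw <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(.CSV_COLS %in% names(raw)))
    stop("roster CSV is missing required columns", call. = FALSE)
  out <- raw[, .CSV_COLS]
  names(out) <- .ROSTER_COLS
  out
}
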