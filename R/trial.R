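## Daily meal plan: clock times shared by all cohorts, grams per age group.
## Trial time starts at the 08:00 breakfast; the 00:00 fifth meal belongs to
## the same daily cycle (960 min after its breakfast), which preserves
## 5 meals/day across the horizon.
.MEAL_CLOCK <- c("08:00", "12:00", "16:00", "20:00", "00:00")
.MEAL_OFFSET <- c(0, 240, 480, 720, 960)  # min after the daily 08:00 start
.MEAL_GRAMS <- list(
  adult      = c(30, 45, 30, 45, 15),
  adolescent = c(30, 45, 45, 45, 30),
  child      = c(30, 30, 30, 30, 15)
)

.METRICS <- c("tir", "tar", "tbr", "pct_below_50", "pct_above_300")
.STRATA <- c("tir100", "tir90")

#' Daily meal plan of a cohort
#'
#' Five meals per day at fixed clock times with age-group-specific
#' carbohydrate content (adults 30/45/30/45/15 g, adolescents
#' 30/45/45/45/30 g, children 30/30/30/30/15 g).
#'
#' @param cohort `"adult"`, `"adolescent"` or `"child"`.
#' @return Data frame with columns `meal`, `clock`, `t_offset_min` (minutes
#'   after the daily 08:00 start) and `cho_true` (g).
#' @export
meal_plan <- function(cohort = c("adult", "adolescent", "child")) {
  cohort <- match.arg(cohort)
  data.frame(meal = seq_along(.MEAL_CLOCK), clock = .MEAL_CLOCK,
             t_offset_min = .MEAL_OFFSET, cho_true = .MEAL_GRAMS[[cohort]],
             stringsAsFactors = FALSE)
}

#' Expand the daily plan into a full trial schedule
#'
#' @param cohort `"adult"`, `"adolescent"` or `"child"`.
#' @param days number of trial days (>= 1).
#' @return Data frame with one row per meal: `day`, `meal`, `clock`, `t_min`
#'   (minutes since the trial start at 08:00 of day 1) and `cho_true` (g).
#' @examples
#' head(build_schedule("adult", 2))
#' @export
build_schedule <- function(cohort, days) {
  if (!is.numeric(days) || length(days) != 1L || days < 1 ||
      days != round(days))
    stop("'days' must be a positive integer", call. = FALSE)
  plan <- meal_plan(cohort)
  out <- do.call(rbind, lapply(seq_len(days), function(d) {
    data.frame(day = d, meal = plan$meal, clock = plan$clock,
               t_min = (d - 1) * 1440 + plan$t_offset_min,
               cho_true = plan$cho_true, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Trial configuration
#'
#' @param days trial length in days (default 90).
#' @param experiments subset of [cc_experiments()] to run; the error-free
#'   control `E0` is always included (it is the comparator).
#' @param thresholds a [glucose_thresholds()] object.
#' @param master_seed integer master seed; every random draw in the trial is
#'   derived from it (see Details).
#' @param n_resamples bootstrap resamples per comparison.
#' @param min_tir control-arm exclusion threshold, percent.
#' @details Reproducibility uses one sub-stream per (experiment, patient):
#'   the seed of each stream is
#'   `(master_seed + 104729 * experiment_number + 7919 * key(id)) mod (2^31 - 1)`
#'   where `key(id)` is a position-weighted character sum of the patient id.
#'   Each (patient, experiment) cell can therefore be re-run in isolation.
#'   Bootstrap comparisons use an analogous scheme over (experiment, metric,
#'   stratum).
#' @return An object of class `trial_config`.
#' @export
trial_config <- function(days = 90, experiments = cc_experiments(),
                         thresholds = glucose_thresholds(),
                         master_seed = 1L, n_resamples = 10000,
                         min_tir = 90) {
  if (!is.numeric(days) || length(days) != 1L || days < 1 ||
      days != round(days))
    stop("'days' must be a positive integer", call. = FALSE)
  bad <- setdiff(experiments, cc_experiments())
  if (length(bad))
    stop("unknown experiments: ", paste(bad, collapse = ", "), call. = FALSE)
  experiments <- cc_experiments()[cc_experiments() %in%
                                    union("E0", experiments)]
  if (!is.numeric(master_seed) || length(master_seed) != 1L ||
      master_seed != round(master_seed))
    stop("'master_seed' must be an integer", call. = FALSE)
  structure(list(days = as.integer(days), experiments = experiments,
                 thresholds = thresholds,
                 master_seed = as.integer(master_seed),
                 n_resamples = as.integer(n_resamples),
                 min_tir = min_tir),
            class = "trial_config")
}

#' @export
print.trial_config <- function(x, ...) {
  cat(sprintf("Trial config: %d days, experiments %s, master seed %d, %d resamples, exclusion TIR < %g%%\n",
              x$days, paste(x$experiments, collapse = " "), x$master_seed,
              x$n_resamples, x$min_tir))
  invisible(x)
}

## deterministic position-weighted key of a patient id
.id_key <- function(id) sum(utf8ToInt(id) * seq_along(utf8ToInt(id)))

.sub_seed <- function(master_seed, experiment, id) {
  expnum <- as.integer(substring(experiment, 2))
  as.integer((as.double(master_seed) + 104729 * expnum +
                7919 * .id_key(id)) %% 2147483647)
}

.boot_seed <- function(master_seed, experiment, metric, stratum) {
  expnum <- as.integer(substring(experiment, 2))
  as.integer((as.double(master_seed) + 1009 * expnum +
                131 * match(metric, .METRICS) +
                17 * match(stratum, .STRATA)) %% 2147483647)
}

#' Run one (patient, experiment) cell of the trial
#'
#' Simulates the full horizon for one calibrated patient under one
#' error-injection scenario.  One counting error is drawn per meal from the
#' experiment's distribution; every bolus is computed from the estimated
#' carbohydrates and the simulated preprandial glucose at the meal instant
#' (insulin on board taken as 0, the meal spacing being wide enough for the
#' previous bolus to have decayed).
#'
#' @param patient one roster row (data frame with `id`, `cohort`, `icr`,
#'   `isf`, `delta_cho_max`, `basal`).
#' @param experiment one of [cc_experiments()].
#' @param config a [trial_config()] object.
#' @param params calibrated [metabolic_params()] for this patient; computed
#'   by [calibrate_patient()] when `NULL`.
#' @param template template passed to [calibrate_patient()] when `params` is
#'   `NULL`.
#' @param keep_trace retain the full glucose trace in the result.
#' @return A list with `outcome` (one-row data frame: `id`, `cohort`,
#'   `experiment`, the five metrics), `meals` (per-meal log with `cho_true`,
#'   `delta_cho`, `cho_estimated`, `g_preprandial`, `bolus`), `seed`, and
#'   optionally `trace`.
#' @export
run_experiment <- function(patient, experiment, config = trial_config(),
                           params = NULL, template = metabolic_params(),
                           keep_trace = FALSE) {
  patient <- as.data.frame(patient)
  stopifnot(nrow(patient) == 1,
            all(c("id", "cohort", "icr", "isf", "delta_cho_max", "basal")
                %in% names(patient)))
  therapy <- therapy_params(patient$icr, patient$isf)
  if (is.null(params))
    params <- calibrate_patient(therapy, template)
  sched <- build_schedule(patient$cohort, config$days)
  spec <- build_error_spec(experiment, patient$delta_cho_max)
  seed <- .sub_seed(config$master_seed, experiment, patient$id)
  delta <- sample_errors(spec, nrow(sched), seed = seed)
  gt <- config$thresholds$g_target
  horizon <- config$days * 1440

  ## first meal falls at t = 0: fold it into the initial state, with the
  ## preprandial glucose equal to the fasting equilibrium
  y0 <- .cc_state0(params, patient$basal, g0 = params$g_b)
  che1 <- estimate_cho(sched$cho_true[1], delta[1])
  bol1 <- compute_bolus(che1, y0[["G"]], therapy,
                        thresholds = config$thresholds)
  y0[["Q1"]] <- params$bioavail * sched$cho_true[1] * 1000
  y0[["Isc1"]] <- y0[["Isc1"]] + bol1

  ev <- cbind(sched$t_min[-1], sched$cho_true[-1], delta[-1])
  times <- seq(0, horizon, by = .CGM_DT)
  out <- tryCatch(
    .cc_run(y0, times, params, patient$basal, mode = 1, events = ev,
            icr = therapy$icr, isf = therapy$isf, g_target = gt, iob = 0),
    error = function(e) stop(sprintf("patient %s, experiment %s: %s",
                                     patient$id, experiment,
                                     conditionMessage(e)), call. = FALSE))
  out <- out[-nrow(out), , drop = FALSE]
  g <- out[, "G"]
  if (any(g <= 0))
    stop(sprintf("patient %s, experiment %s: simulated glucose became non-positive",
                 patient$id, experiment), call. = FALSE)

  g_pre <- g[match(sched$t_min, out[, "time"])]
  che <- estimate_cho(sched$cho_true, delta)
  bolus <- pmax(0, che / therapy$icr + (g_pre - gt) / therapy$isf)
  meals <- data.frame(sched, delta_cho = delta, cho_estimated = che,
                      g_preprandial = g_pre, bolus = bolus)
  outcome <- data.frame(id = patient$id, cohort = patient$cohort,
                        experiment = experiment,
                        compute_metrics(g), stringsAsFactors = FALSE)
  res <- list(outcome = outcome, meals = meals, seed = seed)
  if (keep_trace) {
    tr <- data.frame(t_min = out[, "time"], glucose_mgdl = g)
    class(tr) <- c("glucose_trace", "data.frame")
    res$trace <- tr
  }
  res
}

#' Run the full in-silico trial
#'
#' The package's main entry point.  For every roster subject the metabolic
#' model is calibrated to the subject's ICR/ISF, then every configured
#' error-injection experiment is simulated over the full horizon; outcome
#' metrics are computed per (patient, experiment), the control-arm exclusion
#' and the two analysis strata are applied, and every experiment is compared
#' with the error-free control by paired bootstrap, per metric and stratum.
#'
#' @param config a [trial_config()] object.
#' @param roster a roster data frame; defaults to the 33-subject reference
#'   roster.
#' @param template shared [metabolic_params()] kinetics template.
#' @param out_dir optional directory; when given, `metrics.csv`,
#'   `comparisons.csv`, `roster.csv` and `manifest.csv` (plus `meal_log.csv`
#'   if `keep_meal_logs`) are written there, byte-reproducibly for a fixed
#'   `master_seed`.
#' @param keep_meal_logs retain (and write) the per-meal logs of every cell.
#' @param progress print per-patient progress messages.
#' @return An object of class `cc_trial`: list with `outcomes` (per
#'   patient x experiment metrics), `comparisons` (bootstrap results per
#'   experiment x metric x stratum), `strata`, `calibration` (per-patient
#'   `si`, `v_g`), `roster`, `config`, and optionally `meal_logs`.
#' @examples
#' \donttest{
#' cfg <- trial_config(days = 5, experiments = c("E0", "E8"),
#'                     master_seed = 7, n_resamples = 500)
#' fit <- run_trial(cfg, roster = load_reference_roster()[c(1, 12, 23), ])
#' summary(fit)
#' }
#' @export
run_trial <- function(config = trial_config(),
                      roster = load_reference_roster(),
                      template = metabolic_params(), out_dir = NULL,
                      keep_meal_logs = FALSE, progress = FALSE) {
  if (!inherits(config, "trial_config"))
    stop("'config' must be a trial_config object", call. = FALSE)
  t0 <- proc.time()[["elapsed"]]

  cal <- vector("list", nrow(roster))
  names(cal) <- roster$id
  for (i in seq_len(nrow(roster))) {
    cal[[i]] <- calibrate_patient(therapy_params(roster$icr[i],
                                                 roster$isf[i]), template)
    if (progress) message("calibrated ", roster$id[i])
  }
  calibration <- data.frame(id = roster$id,
                            si = vapply(cal, `[[`, 0, "si"),
                            v_g = vapply(cal, `[[`, 0, "v_g"),
                            stringsAsFactors = FALSE)
  rownames(calibration) <- NULL

  cells <- vector("list", nrow(roster) * length(config$experiments))
  logs <- if (keep_meal_logs) vector("list", length(cells))
  k <- 0
  for (i in seq_len(nrow(roster))) {
    for (ex in config$experiments) {
      k <- k + 1
      cell <- run_experiment(roster[i, ], ex, config, params = cal[[i]])
      cells[[k]] <- cell$outcome
      if (keep_meal_logs)
        logs[[k]] <- data.frame(id = roster$id[i], experiment = ex,
                                cell$meals, stringsAsFactors = FALSE)
    }
    if (progress) message("simulated ", roster$id[i])
  }
  outcomes <- do.call(rbind, cells)
  rownames(outcomes) <- NULL

  e0 <- outcomes[outcomes$experiment == "E0", c("id", "tir")]
  strata <- exclude_subjects(e0, config$min_tir)

  comparisons <- .compare_to_control(outcomes, strata, config)

  res <- structure(list(
    outcomes = outcomes, comparisons = comparisons, strata = strata,
    calibration = calibration, roster = roster, config = config,
    elapsed_s = proc.time()[["elapsed"]] - t0
  ), class = "cc_trial")
  if (keep_meal_logs) res$meal_logs <- do.call(rbind, logs)
  if (!is.null(out_dir)) .write_trial(res, out_dir)
  res
}

.compare_to_control <- function(outcomes, strata, config) {
  exps <- setdiff(config$experiments, "E0")
  rows <- list()
  for (ex in exps) {
    for (st in .STRATA) {
      ids <- strata[[st]]
      if (length(ids) < 2) next
      a <- outcomes[outcomes$experiment == ex & outcomes$id %in% ids, ]
      b <- outcomes[outcomes$experiment == "E0" & outcomes$id %in% ids, ]
      a <- a[match(ids, a$id), ]
      b <- b[match(ids, b$id), ]
      for (m in .METRICS) {
        seed <- .boot_seed(config$master_seed, ex, m, st)
        bt <- bootstrap_paired_diff(a[[m]], b[[m]],
                                    n_resamples = config$n_resamples,
                                    seed = seed)
        rows[[length(rows) + 1]] <- data.frame(
          experiment = ex, stratum = st, metric = m,
          mean_diff = bt$mean_diff, ci_low = bt$ci_low,
          ci_high = bt$ci_high, p_value = bt$p_value,
          n_subjects = bt$n_subjects, n_resamples = bt$n_resamples,
          seed = seed, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows))
    return(data.frame(experiment = character(), stratum = character(),
                      metric = character(), mean_diff = numeric(),
                      ci_low = numeric(), ci_high = numeric(),
                      p_value = numeric(), n_subjects = integer(),
                      n_resamples = integer(), seed = integer(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

.write_trial <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- res$config
  write.csv(res$outcomes, file.path(out_dir, "metrics.csv"),
            row.names = FALSE, quote = FALSE)
  write.csv(res$comparisons, file.path(out_dir, "comparisons.csv"),
            row.names = FALSE, quote = FALSE)
  write_roster(res$roster, file.path(out_dir, "roster.csv"))
  if (!is.null(res$meal_logs))
    write.csv(res$meal_logs, file.path(out_dir, "meal_log.csv"),
              row.names = FALSE, quote = FALSE)
  desc <- paste(cfg$days, cfg$master_seed, cfg$n_resamples, cfg$min_tir,
                paste(cfg$experiments, collapse = ";"),
                paste(res$roster$id, collapse = ";"))
  manifest <- data.frame(
    key = c("package", "version", "days", "experiments", "master_seed",
            "n_resamples", "min_tir", "n_patients", "excluded",
            "config_checksum"),
    value = c("carbsafe",
              as.character(utils::packageVersion("carbsafe")),
              cfg$days, paste(cfg$experiments, collapse = ";"),
              cfg$master_seed, cfg$n_resamples, cfg$min_tir,
              nrow(res$roster),
              paste(res$strata$excluded, collapse = ";"),
              sum(utf8ToInt(desc))),
    stringsAsFactors = FALSE)
  write.csv(manifest, file.path(out_dir, "manifest.csv"),
            row.names = FALSE, quote = FALSE)
  invisible(out_dir)
}

#' @export
print.cc_trial <- function(x, ...) {
  cat(sprintf("In-silico CC-error trial: %d patients x %d experiments x %d days\n",
              nrow(x$roster), length(x$config$experiments), x$config$days))
  cat(sprintf("Excluded (control TIR < %g%%): %s\n", x$config$min_tir,
              if (length(x$strata$excluded))
                paste(x$strata$excluded, collapse = ", ") else "none"))
  cat(sprintf("Strata: TIR == 100%%: n = %d; TIR >= %g%%: n = %d\n",
              length(x$strata$tir100), x$config$min_tir,
              length(x$strata$tir90)))
  mt <- tapply(x$outcomes$tir, x$outcomes$experiment, mean)
  mt <- mt[x$config$experiments]
  cat("Mean TIR (%) by experiment:\n")
  print(round(mt, 2))
  invisible(x)
}

#' Summarize a trial: mean metric differences from the control arm
#'
#' @param object a [run_trial()] result.
#' @param ... unused.
#' @return An object of class `summary.cc_trial` wrapping the comparison
#'   table and headline aggregates.
#' @export
summary.cc_trial <- function(object, ...) {
  cmp <- object$comparisons
  structure(list(comparisons = cmp, strata = object$strata,
                 config = object$config), class = "summary.cc_trial")
}

#' @export
print.summary.cc_trial <- function(x, ...) {
  if (!nrow(x$comparisons)) {
    cat("No comparisons (control arm only).\n")
    return(invisible(x))
  }
  for (st in unique(x$comparisons$stratum)) {
    n <- x$comparisons$n_subjects[x$comparisons$stratum == st][1]
    cat(sprintf("\nStratum %s (n = %d): mean difference vs E0 (95%% CI)\n",
                st, n))
    sub <- x$comparisons[x$comparisons$stratum == st &
                           x$comparisons$metric %in% c("tir", "tar", "tbr"), ]
    for (ex in unique(sub$experiment)) {
      r <- sub[sub$experiment == ex, ]
      cat(sprintf("  %s:  %s\n", ex, paste(sprintf(
        "%s %+.2f [%+.2f, %+.2f]", toupper(r$metric), r$mean_diff,
        r$ci_low, r$ci_high), collapse = "  ")))
    }
  }
  invisible(x)
}

#' Plot metric differences against the control arm
#'
#' Bar plot of the mean per-subject difference of a metric in each
#' experiment relative to the error-free control, with percentile bootstrap
#' confidence intervals as whiskers -- the trial's headline figure.
#'
#' @param x a [run_trial()] result.
#' @param metric one of `"tir"`, `"tar"`, `"tbr"`, `"pct_below_50"`,
#'   `"pct_above_300"`.
#' @param stratum `"tir90"` (all retained subjects) or `"tir100"`.
#' @param ... passed to [graphics::barplot()].
#' @return Invisibly, the plotted subset of the comparison table.
#' @export
plot.cc_trial <- function(x, metric = "tir", stratum = "tir90", ...) {
  metric <- match.arg(metric, .METRICS)
  stratum <- match.arg(stratum, .STRATA)
  cmp <- x$comparisons
  sub <- cmp[cmp$metric == metric & cmp$stratum == stratum, ]
  if (!nrow(sub)) stop("no comparisons for this metric/stratum",
                       call. = FALSE)
  ylim <- range(0, sub$ci_low, sub$ci_high)
  mid <- barplot(sub$mean_diff, names.arg = sub$experiment,
                 ylim = ylim + c(-1, 1) * 0.05 * diff(ylim),
                 ylab = sprintf("%s difference vs E0 (percentage points)",
                                toupper(metric)),
                 main = sprintf("stratum %s", stratum), ...)
  arrows(mid, sub$ci_low, mid, sub$ci_high, angle = 90, code = 3,
         length = 0.04)
  abline(h = 0)
  invisible(sub)
}
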