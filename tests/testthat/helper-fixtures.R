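# Shared fixtures: a small cross-cohort roster and a calibration cache so
# repeated tests do not re-run the bisection searches.

tiny_roster <- function() {
  r <- load_reference_roster()
  r[r$id %in% c("Adult#1", "Adolescent#5", "Child#4"), ]
}

.cal_cache <- new.env(parent = emptyenv())

cached_calibration <- function(icr, isf, template = metabolic_params()) {
  key <- paste(icr, isf, sep = "|")
  if (is.null(.cal_cache[[key]]))
    .cal_cache[[key]] <- calibrate_patient(therapy_params(icr, isf), template)
  .cal_cache[[key]]
}

# deterministic small trial for orchestration tests
small_config <- function(...) {
  trial_config(days = 3, experiments = c("E0", "E1", "E8", "E9"),
               master_seed = 11, n_resamples = 400, ...)
}
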