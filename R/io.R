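# Session logs, cohort/config files and deterministic test fixtures.
#
# Logs are RFC-4180 CSV (UTF-8, '.' decimal) with a JSON side-car summary so
# every result is traceable to the exact configuration (config hash) and
# seed. Workloads are stored in modality units with an explicit units column
# to keep logs readable for sport scientists.

session_csv_columns <- c("step_index", "phase", "workload", "workload_units",
                         "duration_min", "lactate_mM", "hr_bpm", "rpe",
                         "decision", "timestamp_min")

#' Write a session record to CSV (+ JSON side-car)
#'
#' The CSV holds one row per protocol step with columns
#' `step_index, phase, workload, workload_units, duration_min, lactate_mM,
#' hr_bpm, rpe, decision, timestamp_min`. A side-car `<path without ext>.json`
#' stores the outcome summary: fired criterion, MLSS workload estimate
#' (`null` for invalid sessions), outcome, seed and configuration hash.
#'
#' @param record an `ilt_session` from [run_ilt_test()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_session <- function(record, path) {
  stopifnot(inherits(record, "ilt_session"))
  units <- if (record$config$modality == "running") "m/s" else "W"
  s <- record$steps
  df <- if (nrow(s) == 0) {
    stats::setNames(as.data.frame(matrix(nrow = 0, ncol = 10)),
                    session_csv_columns)
  } else {
    data.frame(step_index = s$index, phase = s$phase, workload = s$workload,
               workload_units = units, duration_min = s$duration,
               lactate_mM = s$lactate, hr_bpm = s$hr, rpe = s$rpe,
               decision = s$decision, timestamp_min = s$timestamp,
               stringsAsFactors = FALSE)
  }
  utils::write.csv(df, path, row.names = FALSE)
  th <- record$threshold
  summary <- list(
    subject_id = record$subject_id,
    outcome = record$outcome,
    mlss_workload_estimate = record$mlss_workload_estimate,
    threshold = list(criterion = th$criterion, trigger_step = th$trigger_step,
                     reference_step = th$reference_step,
                     delta_lactate = th$delta_lactate,
                     lt_workload = th$lt_workload, lt_lactate = th$lt_lactate),
    verification_attempts = record$verification_attempts,
    seed = record$seed,
    config_hash = record$config_hash,
    workload_units = units
  )
  jsonlite::write_json(summary, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}

sidecar_path <- function(path) {
  paste0(tools::file_path_sans_ext(path), ".json")
}

#' Read a session log written by [write_session()] or recorded externally
#'
#' Validates the header and every row; malformed rows are reported with their
#' line number. Externally recorded logs only need `step_index`, `workload`,
#' `workload_units`, `duration_min` and `lactate_mM`; the remaining columns
#' are optional. If a JSON side-car is present its summary is attached.
#'
#' @param path CSV path.
#' @return an `ilt_session_log`: list with `steps` (internal step data frame
#'   usable by [classify_steps()]), `workload_units`, and `summary` (side-car
#'   contents or `NULL`).
#' @export
read_session <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("step_index", "workload", "workload_units", "duration_min",
                "lactate_mM")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop_domain("session log missing columns: ", paste(missing, collapse = ", "))
  if (nrow(df) > 0) {
    bad <- which(!is.finite(df$lactate_mM) | df$lactate_mM < 0)
    if (length(bad))
      stop_domain("invalid lactate_mM at row(s) ",
                  paste(bad + 1L, collapse = ", "),
                  " of ", basename(path), " (header is row 1)")
    if (length(unique(df$workload_units)) > 1)
      stop_domain("mixed workload units in ", basename(path))
  }
  steps <- data.frame(
    index = as.integer(df$step_index),
    phase = df$phase %||% rep("fine_adaptation", nrow(df)),
    workload = df$workload,
    duration = df$duration_min,
    lactate = df$lactate_mM,
    hr = df$hr_bpm %||% rep(NA_real_, nrow(df)),
    rpe = df$rpe %||% rep(NA_real_, nrow(df)),
    decision = df$decision %||% rep(NA_character_, nrow(df)),
    timestamp = df$timestamp_min %||% rep(NA_real_, nrow(df)),
    stringsAsFactors = FALSE
  )
  side <- sidecar_path(path)
  summary <- if (file.exists(side)) jsonlite::read_json(side) else NULL
  structure(list(steps = steps,
                 workload_units = if (nrow(df)) df$workload_units[1] else NA,
                 summary = summary, path = path),
            class = "ilt_session_log")
}

#' Write a batch of sessions plus one summary index
#'
#' @param records list of `ilt_session` objects.
#' @param dir output directory (created if needed).
#' @return path of the index CSV, invisibly.
#' @export
write_session_batch <- function(records, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(seq_along(records), function(i) {
    rec <- records[[i]]
    file <- sprintf("session_%03d_%s.csv", i, rec$subject_id)
    write_session(rec, file.path(dir, file))
    data.frame(file = file, subject_id = rec$subject_id,
               outcome = rec$outcome, criterion = rec$threshold$criterion,
               mlss_workload_estimate = rec$mlss_workload_estimate,
               seed = rec$seed, stringsAsFactors = FALSE)
  })
  index <- file.path(dir, "session_index.csv")
  utils::write.csv(do.call(rbind, rows), index, row.names = FALSE)
  invisible(index)
}

#' Read a protocol configuration from JSON
#'
#' Unknown fields are rejected; missing fields take the
#' [protocol_config()] defaults.
#'
#' @param path JSON file.
#' @return a `protocol_config`.
#' @export
read_protocol_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(protocol_config))
  unknown <- setdiff(names(x), known)
  if (length(unknown))
    stop_domain("unknown config fields: ", paste(unknown, collapse = ", "))
  do.call(protocol_config, x)
}

#' Write a protocol configuration to JSON
#'
#' @param config a [protocol_config()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_protocol_config <- function(config, path) {
  drop <- c("quantum")  # derived from modality on read
  jsonlite::write_json(unclass(config)[setdiff(names(config), drop)], path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

# Hand-built subject used for the deterministic fixtures: warm-up settles at
# 3.2 m/s ((140 - 60)/25), so a ta_intercept of 0.95 puts the first workload
# exactly 0.15 m/s above the true MLSS of 4.0 -> overshoot correction path.
fixture_subject <- function(lag = 0L) {
  subject_profile(id = "FIX", age = 30, modality = "running",
                  mlss_workload = 4.0, baseline_lactate = 1.2,
                  sub_threshold_gain = 0.35, supra_threshold_rate = 10,
                  lactate_time_constant = 2, accumulation_lag_steps = lag,
                  hr_rest = 60, hr_gain = 25, hr_time_constant = 1,
                  rpe_at_mlss = 5)
}

# A synthetic delayed-criterion log: increment to 3.6 m/s with a 0.45 mM jump
# (just below TC1), then a slow drift whose cumulative rise first exceeds
# 0.4 mM at the 8th constant-workload step.
fixture_tc2_delayed_steps <- function() {
  la <- c(2.20, 2.45, 2.90, 2.95, 3.00, 3.05, 3.10, 3.15, 3.20, 3.25, 3.35)
  data.frame(
    index = seq_along(la) - 1L,
    phase = c("warmup", "fine_adaptation", "fine_adaptation",
              rep("fine_adaptation", 8)),
    workload = c(3.0, 3.3, rep(3.6, 9)),
    duration = c(10, rep(4, 10)),
    lactate = la,
    hr = round(seq(140, 172, length.out = length(la)), 1),
    rpe = round(seq(3.5, 5.5, length.out = length(la)), 1),
    decision = c("warmup_settled", "increase_0.3", rep("hold", 9)),
    timestamp = cumsum(c(10, rep(4, 10))) + 1,
    stringsAsFactors = FALSE
  )
}

# Slow-creep log: three consecutive rises of 0.12/0.12/0.13 mM at constant
# workload, cumulative 0.37 mM (never reaching the steep-rise magnitudes).
fixture_tc2a_steps <- function() {
  la <- c(2.20, 2.48, 2.90, 3.02, 3.14, 3.27)
  data.frame(
    index = seq_along(la) - 1L,
    phase = c("warmup", rep("fine_adaptation", 5)),
    workload = c(3.0, 3.3, rep(3.6, 4)),
    duration = c(10, rep(4, 5)),
    lactate = la,
    hr = round(seq(140, 170, length.out = length(la)), 1),
    rpe = round(seq(3.5, 5.3, length.out = length(la)), 1),
    decision = c("warmup_settled", "increase_0.3", rep("hold", 4)),
    timestamp = cumsum(c(10, rep(4, 5))) + 1,
    stringsAsFactors = FALSE
  )
}

synthetic_log_record <- function(steps, subject_id, seed) {
  cfg <- protocol_config("running")
  th <- classify_steps(steps)
  structure(list(subject_id = subject_id, config = cfg,
                 config_hash = config_hash(unclass(cfg)),
                 steps = steps, threshold = th,
                 mlss_workload_estimate = NA_real_, outcome = "invalid",
                 seed = seed, verification_attempts = 0L),
            class = "ilt_session")
}

#' Generate the deterministic fixture sessions
#'
#' Writes five synthetic sessions (CSV + JSON side-cars) to `dir`:
#' `tc1` (steep rise directly after an increment), `tc2_delayed` (criterion
#' reached at the 8th constant-workload step), `tc2a` (slow creep over three
#' steps), `overshoot` (too-high first workload, corrected, then completed)
#' and `invalid` (abandoned before any criterion). All content is synthetic —
#' generated by the simulator or hand-constructed series — and byte-identical
#' for the same seed.
#'
#' @param dir output directory.
#' @param seed integer seed.
#' @return named character vector of the CSV paths, invisibly.
#' @export
generate_fixtures <- function(dir, seed = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c()
  cfg <- protocol_config("running")

  tc1 <- run_ilt_test(fixture_subject(), cfg, seed = derive_seed(seed, "tc1"))
  paths["tc1"] <- file.path(dir, "tc1_session.csv")
  write_session(tc1, paths["tc1"])

  d2 <- synthetic_log_record(fixture_tc2_delayed_steps(), "FIX-TC2",
                             derive_seed(seed, "tc2"))
  paths["tc2_delayed"] <- file.path(dir, "tc2_delayed_session.csv")
  write_session(d2, paths["tc2_delayed"])

  d2a <- synthetic_log_record(fixture_tc2a_steps(), "FIX-TC2A",
                              derive_seed(seed, "tc2a"))
  paths["tc2a"] <- file.path(dir, "tc2a_session.csv")
  write_session(d2a, paths["tc2a"])

  over_cfg <- protocol_config("running", ta_intercept = 0.95, ta_slope = 0)
  over <- run_ilt_test(fixture_subject(), over_cfg,
                       seed = derive_seed(seed, "overshoot"),
                       model = measurement_model(cv = 0))
  paths["overshoot"] <- file.path(dir, "overshoot_session.csv")
  write_session(over, paths["overshoot"])

  # too-flat staircase: cannot reach the threshold within max_steps
  inv_cfg <- protocol_config("running", max_steps = 6, ta_slope = 0,
                             ta_intercept = 0.05, increment_big = 0.05,
                             increment_small = 0.05)
  inv <- run_ilt_test(fixture_subject(), inv_cfg,
                      seed = derive_seed(seed, "invalid"))
  paths["invalid"] <- file.path(dir, "invalid_session.csv")
  write_session(inv, paths["invalid"])

  invisible(paths)
}
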