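# Virtual subjects: latent physiological parameters and cohort generation.
#
# The subject model is deliberately minimal: below the maximal lactate steady
# state workload (MLSS_W) blood lactate relaxes first-order toward a
# workload-linear steady state; above MLSS_W it accumulates step by step with
# no steady state. That is the simplest model reproducing the behaviours a
# lactate-guided step test must cope with: sub-threshold steady states, a
# steep (0.5-2.4 mM per 4-min step) rise once the threshold is exceeded, and
# a rise that can be delayed by several constant-workload steps.

#' Construct a virtual subject
#'
#' A `subject_profile` carries the latent ground truth of one virtual athlete,
#' most importantly `mlss_workload`, the true maximal lactate steady state
#' workload the protocol tries to recover.
#'
#' @param id opaque identifier.
#' @param age age in years (warm-up heart-rate target is `170 - age`).
#' @param modality `"running"` (workloads in m/s) or `"cycling"` (W).
#' @param mlss_workload true MLSS workload, workload units.
#' @param baseline_lactate resting blood lactate, mM (0.5-2.5).
#' @param sub_threshold_gain slope of the steady-state lactate curve below
#'   MLSS, mM per workload unit (resting reference is workload 0).
#' @param supra_threshold_rate accumulation rate above MLSS, mM per 4-min step
#'   per workload unit of overshoot.
#' @param lactate_time_constant first-order time constant of lactate kinetics,
#'   minutes.
#' @param accumulation_lag_steps integer 0-7; number of constant-workload
#'   steps above MLSS during which accumulation is attenuated (produces the
#'   delayed, TC2-type threshold appearance).
#' @param lag_attenuation fraction of `supra_threshold_rate` active during the
#'   lag (0 < value <= 1). A strictly zero lag response would be invisible to
#'   any lactate-guided controller; the attenuated drift is what the delayed
#'   criterion actually detects.
#' @param hr_rest resting heart rate, bpm.
#' @param hr_gain heart-rate gain, bpm per workload unit.
#' @param hr_time_constant heart-rate time constant, minutes.
#' @param rpe_at_mlss rating of perceived exertion (0-10 Borg scale) at MLSS;
#'   by instruction, effort sustainable for 60 min is reported as 5.
#' @return an object of class `subject_profile`.
#' @export
subject_profile <- function(id, age, modality = c("running", "cycling"),
                            mlss_workload,
                            baseline_lactate = 1.2,
                            sub_threshold_gain,
                            supra_threshold_rate,
                            lactate_time_constant = 2,
                            accumulation_lag_steps = 0L,
                            lag_attenuation = 0.3,
                            hr_rest = 60,
                            hr_gain = 25,
                            hr_time_constant = 1,
                            rpe_at_mlss = 5) {
  modality <- match.arg(modality)
  if (mlss_workload <= 0) stop_domain("mlss_workload must be > 0")
  if (accumulation_lag_steps < 0 || accumulation_lag_steps > 7)
    stop_domain("accumulation_lag_steps must be in 0..7")
  if (lactate_time_constant <= 0 || hr_time_constant <= 0)
    stop_domain("time constants must be > 0")
  if (baseline_lactate < 0.5 || baseline_lactate > 2.5)
    stop_domain("baseline_lactate must be in [0.5, 2.5] mM")
  if (lag_attenuation <= 0 || lag_attenuation > 1)
    stop_domain("lag_attenuation must be in (0, 1]")
  structure(list(
    id = as.character(id), age = age, modality = modality,
    mlss_workload = mlss_workload,
    baseline_lactate = baseline_lactate,
    sub_threshold_gain = sub_threshold_gain,
    supra_threshold_rate = supra_threshold_rate,
    lactate_time_constant = lactate_time_constant,
    accumulation_lag_steps = as.integer(accumulation_lag_steps),
    lag_attenuation = lag_attenuation,
    hr_rest = hr_rest, hr_gain = hr_gain,
    hr_time_constant = hr_time_constant,
    rpe_at_mlss = rpe_at_mlss
  ), class = "subject_profile")
}

#' @export
print.subject_profile <- function(x, ...) {
  unit <- if (x$modality == "running") "m/s" else "W"
  cat(sprintf("<subject_profile %s> %s, MLSS %.2f %s, lag %d, LT-range lactate %.2f mM\n",
              x$id, x$modality, x$mlss_workload, unit,
              x$accumulation_lag_steps,
              steady_state_lactate(x, x$mlss_workload)))
  invisible(x)
}

#' Steady-state lactate below the threshold
#'
#' @param subject a [subject_profile()].
#' @param workload workload units.
#' @return mM; `baseline_lactate + sub_threshold_gain * workload`. Only a true
#'   steady state for `workload <= mlss_workload`; above it the same line is
#'   the (extrapolated) floor the accumulating lactate sits on.
#' @export
steady_state_lactate <- function(subject, workload) {
  subject$baseline_lactate + subject$sub_threshold_gain * pmax(0, workload)
}

#' Lactate analyzer measurement model
#'
#' Multiplicative Gaussian noise with coefficient of variation `cv`
#' (default 3%, the portable analyzer figure). The ~15 s sampling stop and the
#' 60 s analysis time have no effect on the 4-min step dynamics and are kept
#' only for log timestamps.
#'
#' @param cv coefficient of variation as a fraction (0.03 = 3%). `cv = 0`
#'   reproduces true values exactly.
#' @param sampling_pause minutes the treadmill is stopped to sample (0.25).
#' @param measurement_delay minutes until the analyzer reports (1.0).
#' @param rng_seed optional integer seed attached to the model.
#' @return object of class `measurement_model`.
#' @export
measurement_model <- function(cv = 0.03, sampling_pause = 0.25,
                              measurement_delay = 1.0, rng_seed = NULL) {
  if (cv < 0) stop_domain("cv must be >= 0")
  structure(list(cv = cv, sampling_pause = sampling_pause,
                 measurement_delay = measurement_delay, rng_seed = rng_seed),
            class = "measurement_model")
}

#' Fresh physiological state for a subject at rest
#'
#' Carries true lactate, heart rate, the constant-supra-workload step counter
#' (reset whenever the workload changes) and elapsed time between steps.
#'
#' @param subject a [subject_profile()].
#' @return object of class `physio_state`.
#' @export
physio_state <- function(subject) {
  structure(list(
    current_true_lactate = subject$baseline_lactate,
    current_hr = subject$hr_rest,
    steps_at_constant_supra_workload = 0L,
    last_workload = NA_real_,
    elapsed_time = 0
  ), class = "physio_state")
}

#' Default cohort parameter ranges
#'
#' The stated world of the simulator: uniform ranges chosen so that (i) the
#' implied steady-state lactate at MLSS lies in the observed 1.9-5 mM
#' threshold-lactate window, (ii) a 0.1-0.15 m/s (7-10 W) overshoot of MLSS
#' yields a 0.5-2.4 mM per-step rise, and (iii) the warm-up heart-rate target
#' (170 - age) always maps to a workload safely below MLSS. `hr_gain` is
#' specified indirectly through `hr_at_mlss` (heart rate at the MLSS
#' workload) because resting HR, HR gain and MLSS are physiologically coupled.
#'
#' @param modality `"running"` or `"cycling"`.
#' @return named list of `c(lo, hi)` ranges.
#' @export
default_parameter_ranges <- function(modality = c("running", "cycling")) {
  modality <- match.arg(modality)
  common <- list(
    age = c(28, 45),
    baseline_lactate = c(1.0, 1.4),
    lactate_time_constant = c(1.5, 2.5),
    accumulation_lag_steps = c(0, 7),
    lag_attenuation = c(0.3, 0.3),
    hr_rest = c(58, 70),
    hr_at_mlss = c(165, 178),
    hr_time_constant = c(0.8, 1.2),
    rpe_at_mlss = c(4.5, 5.5)
  )
  if (modality == "running") {
    c(list(mlss_workload = c(3.0, 4.8),
           sub_threshold_gain = c(0.30, 0.375),
           supra_threshold_rate = c(10, 16)), common)
  } else {
    c(list(mlss_workload = c(150, 350),
           sub_threshold_gain = c(0.006, 0.009),
           supra_threshold_rate = c(0.07, 0.16)), common)
  }
}

#' Generate a seeded cohort of virtual subjects
#'
#' Parameters are drawn uniformly and independently from per-field ranges.
#' `mlss_workload` is snapped to the modality workload quantum: the MLSS
#' workload is operationally defined only at the resolution of the protocol.
#' Every generated subject is checked against the `subject_profile`
#' invariants, including the implied threshold-range lactate (1.9-5 mM at
#' MLSS); ranges that can produce a violating subject are rejected.
#'
#' @param n cohort size (>= 1).
#' @param modality `"running"` or `"cycling"`.
#' @param parameter_ranges named list of `c(lo, hi)`; see
#'   [default_parameter_ranges()].
#' @param seed integer root seed; the cohort stream is derived from it, so the
#'   same seed always yields the identical cohort.
#' @return list of [subject_profile()] objects, class `ilt_cohort`.
#' @export
make_cohort <- function(n, modality = c("running", "cycling"),
                        parameter_ranges = default_parameter_ranges(modality),
                        seed = 1) {
  modality <- match.arg(modality)
  if (n < 1) stop_domain("n must be >= 1")
  r <- utils::modifyList(default_parameter_ranges(modality), parameter_ranges)
  for (nm in names(r)) {
    if (length(r[[nm]]) != 2 || any(!is.finite(r[[nm]])) || r[[nm]][1] > r[[nm]][2])
      stop_domain("invalid range for ", nm)
  }
  # reject ranges whose extremes violate the threshold-lactate invariant
  ss_lo <- r$baseline_lactate[1] + r$sub_threshold_gain[1] * r$mlss_workload[1]
  ss_hi <- r$baseline_lactate[2] + r$sub_threshold_gain[2] * r$mlss_workload[2]
  if (ss_lo < 1.9 - 1e-9 || ss_hi > 5 + 1e-9)
    stop_domain("ranges imply steady-state lactate at MLSS outside [1.9, 5] mM")
  q <- workload_quantum(modality)
  draw <- function(rg) stats::runif(1, rg[1], rg[2])
  subjects <- with_seed(derive_seed(seed, "cohort", modality), {
    lapply(seq_len(n), function(i) {
      hr_rest <- draw(r$hr_rest)
      mlss <- quantize_workload(draw(r$mlss_workload), q)
      hr_at_mlss <- draw(r$hr_at_mlss)
      subject_profile(
        id = sprintf("S%03d", i),
        age = round(draw(r$age)),
        modality = modality,
        mlss_workload = mlss,
        baseline_lactate = draw(r$baseline_lactate),
        sub_threshold_gain = draw(r$sub_threshold_gain),
        supra_threshold_rate = draw(r$supra_threshold_rate),
        lactate_time_constant = draw(r$lactate_time_constant),
        accumulation_lag_steps = as.integer(min(r$accumulation_lag_steps[2],
          floor(stats::runif(1, r$accumulation_lag_steps[1],
                             r$accumulation_lag_steps[2] + 1)))),
        lag_attenuation = draw(r$lag_attenuation),
        hr_rest = hr_rest,
        hr_gain = (hr_at_mlss - hr_rest) / mlss,
        hr_time_constant = draw(r$hr_time_constant),
        rpe_at_mlss = draw(r$rpe_at_mlss)
      )
    })
  })
  structure(subjects, class = "ilt_cohort", modality = modality, seed = seed)
}

#' @export
print.ilt_cohort <- function(x, ...) {
  mlss <- vapply(x, `[[`, numeric(1), "mlss_workload")
  cat(sprintf("<ilt_cohort> n = %d %s subjects, MLSS %.2f-%.2f\n",
              length(x), attr(x, "modality"), min(mlss), max(mlss)))
  invisible(x)
}

cohort_columns <- c("id", "modality", "age", "mlss_workload", "baseline_lactate",
                    "sub_threshold_gain", "supra_threshold_rate",
                    "lactate_time_constant", "accumulation_lag_steps",
                    "lag_attenuation", "hr_rest", "hr_gain",
                    "hr_time_constant", "rpe_at_mlss")

#' Export a cohort to CSV (one subject per row)
#'
#' Columns are the `subject_profile` fields in documented units (workloads in
#' m/s or W according to `modality`, lactate in mM, heart rate in bpm, time
#' constants in minutes).
#'
#' @param cohort an `ilt_cohort` or list of subjects.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  df <- do.call(rbind, lapply(cohort, function(s)
    as.data.frame(s[cohort_columns], stringsAsFactors = FALSE)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Import a cohort written by [write_cohort()]
#'
#' @param path CSV file with one subject per row.
#' @return an `ilt_cohort`.
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(cohort_columns, names(df))
  if (length(missing))
    stop_domain("cohort file missing columns: ", paste(missing, collapse = ", "))
  subjects <- lapply(seq_len(nrow(df)), function(i) {
    row <- as.list(df[i, ])
    do.call(subject_profile, row)
  })
  structure(subjects, class = "ilt_cohort", modality = subjects[[1]]$modality)
}
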