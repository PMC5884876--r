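# Closed-loop adaptive threshold test: warm-up -> threshold adaptation ->
# fine threshold adaptation -> threshold detection -> MLSS verification.

#' Protocol configuration with modality defaults
#'
#' All tunables of the adaptive step test. Defaults are the protocol values:
#' 4-min steps, warm-up at heart rate `170 - age`, fine increments of
#' 0.15/0.10 m/s (10/7 W), threshold criteria at 0.5/0.4 mM, verification by a
#' 0.1 m/s (7 W) reduction with a 0.2 mM steadiness tolerance.
#'
#' @param modality `"running"` or `"cycling"`.
#' @param step_duration minutes per protocol step (4).
#' @param warmup_hr_offset warm-up HR target is `warmup_hr_offset - age` (170).
#' @param warmup_duration maximum warm-up length, minutes.
#' @param warmup_tick control-loop tick of the automated warm-up, minutes.
#' @param ta_slope,ta_intercept first-increment mapping: the workload after
#'   the warm-up is `w + max(quantum, ta_slope * w + ta_intercept)`, rounded
#'   to the workload quantum. The published protocol uses an unpublished
#'   regression here; the defaults land the first workload 0.2-0.5 m/s below
#'   a default cohort's MLSS, per its stated intent.
#' @param increment_big,increment_small fine-adaptation increments applied
#'   while the previous step's lactate delta is below `fta_low` /, between
#'   `fta_low` and `fta_high`.
#' @param fta_low,fta_high band edges (mM) of the fine-adaptation rule table.
#' @param verification_reduction workload reduction used to verify the MLSS
#'   workload (0.1 m/s or 7 W).
#' @param verification_tolerance maximal lactate rise (mM) over a verification
#'   step still counted as "accumulation stopped" (0.2).
#' @param max_verification_attempts reductions attempted before the session is
#'   declared invalid (2).
#' @param overshoot_cutoff,overshoot_lactate a first post-adaptation step with
#'   a delta above `overshoot_cutoff` (1 mM) or absolute lactate above
#'   `overshoot_lactate` (5 mM, the upper threshold-lactate bound) triggers a
#'   workload correction.
#' @param overshoot_quanta size of that correction in workload quanta (2).
#' @param max_steps maximum number of post-warm-up steps before the session is
#'   abandoned (20).
#' @param tc1_threshold,tc2_threshold,tc2_window,rise_epsilon,tc2a_cap
#'   threshold-criterion parameters, see [classify_steps()].
#' @param exhaustion_extension if `TRUE`, append one supra-threshold step
#'   after successful verification (demonstration only; it does not affect the
#'   MLSS estimate).
#' @return object of class `protocol_config`.
#' @export
protocol_config <- function(modality = c("running", "cycling"),
                            step_duration = 4,
                            warmup_hr_offset = 170,
                            warmup_duration = 15,
                            warmup_tick = 0.25,
                            ta_slope = 0.10,
                            ta_intercept = NULL,
                            increment_big = NULL,
                            increment_small = NULL,
                            fta_low = 0.2,
                            fta_high = 0.4,
                            verification_reduction = NULL,
                            verification_tolerance = 0.2,
                            max_verification_attempts = 2,
                            overshoot_cutoff = 1.0,
                            overshoot_lactate = 5.0,
                            overshoot_quanta = 2,
                            max_steps = 20,
                            tc1_threshold = 0.5,
                            tc2_threshold = 0.4,
                            tc2_window = 8,
                            rise_epsilon = 0.1,
                            tc2a_cap = 0.5,
                            exhaustion_extension = FALSE) {
  modality <- match.arg(modality)
  running <- modality == "running"
  cfg <- list(
    modality = modality,
    quantum = workload_quantum(modality),
    step_duration = step_duration,
    warmup_hr_offset = warmup_hr_offset,
    warmup_duration = warmup_duration,
    warmup_tick = warmup_tick,
    ta_slope = ta_slope,
    ta_intercept = ta_intercept %||% (if (running) 0.05 else 5),
    increment_big = increment_big %||% (if (running) 0.15 else 10),
    increment_small = increment_small %||% (if (running) 0.10 else 7),
    fta_low = fta_low,
    fta_high = fta_high,
    verification_reduction = verification_reduction %||% (if (running) 0.1 else 7),
    verification_tolerance = verification_tolerance,
    max_verification_attempts = max_verification_attempts,
    overshoot_cutoff = overshoot_cutoff,
    overshoot_lactate = overshoot_lactate,
    overshoot_quanta = overshoot_quanta,
    max_steps = max_steps,
    tc1_threshold = tc1_threshold,
    tc2_threshold = tc2_threshold,
    tc2_window = tc2_window,
    rise_epsilon = rise_epsilon,
    tc2a_cap = tc2a_cap,
    exhaustion_extension = exhaustion_extension
  )
  if (cfg$max_steps < 6) stop_domain("max_steps must be >= 6")
  if (cfg$verification_reduction <= 0) stop_domain("verification_reduction must be > 0")
  structure(cfg, class = "protocol_config")
}

#' @export
print.protocol_config <- function(x, ...) {
  cat(sprintf("<protocol_config> %s, steps %g min, increments +%g/+%g, verify -%g (tol %g mM)\n",
              x$modality, x$step_duration, x$increment_big, x$increment_small,
              x$verification_reduction, x$verification_tolerance))
  invisible(x)
}

#' Automated warm-up at a heart-rate target
#'
#' Runs a proportional feedback loop that adjusts the workload every
#' `warmup_tick` minutes until simulated heart rate stays within 2 bpm of
#' `warmup_hr_offset - age` for one full minute. Returns the settled workload
#' (snapped to the quantum), the end-of-warm-up measured lactate and the
#' updated physiological state.
#'
#' @param subject a [subject_profile()].
#' @param config a [protocol_config()].
#' @param model a [measurement_model()]; the final lactate reading uses the
#'   caller's RNG stream.
#' @param state optional starting [physio_state()].
#' @return list with `workload`, `lactate` (measured, mM), `hr`, `duration`
#'   (minutes) and `state`.
#' @export
run_warmup <- function(subject, config = protocol_config(subject$modality),
                       model = measurement_model(), state = physio_state(subject)) {
  target <- config$warmup_hr_offset - subject$age
  if (target <= subject$hr_rest + 2)
    stop_domain("warm-up HR target ", target, " bpm not above resting HR")
  tick <- config$warmup_tick
  kp <- 0.8 / subject$hr_gain
  # belt-speed / resistance ramp limit per tick, so the initial error cannot
  # slam the workload past the target and induce HR oscillation
  ramp <- if (config$modality == "running") 0.2 else 15
  w <- max(0, 0.5 * (target - subject$hr_rest) / subject$hr_gain)
  settled <- 0
  need <- ceiling(1.5 / tick)  # at least one full minute inside the band
  elapsed <- 0
  while (elapsed < config$warmup_duration) {
    state <- advance_step(subject, state, w, tick)
    elapsed <- elapsed + tick
    err <- target - state$current_hr
    # settle band: within 2 bpm, tightened so the implied workload error is
    # below half a quantum before the warm-up is called settled
    band <- min(2, max(0.25, 0.4 * config$quantum * subject$hr_gain))
    if (abs(err) <= band) settled <- settled + 1 else settled <- 0
    if (settled >= need) break
    w <- max(0, w + max(-ramp, min(ramp, kp * err)))
  }
  if (settled < need)
    stop_domain("warm-up HR target not reached within ", config$warmup_duration,
                " min")
  w <- quantize_workload(w, config$quantum)
  list(workload = w,
       lactate = measure_lactate(state$current_true_lactate, model),
       hr = state$current_hr,
       duration = elapsed,
       state = state)
}

#' First workload after the warm-up (threshold adaptation)
#'
#' `warmup_workload + max(quantum, ta_slope * warmup_workload + ta_intercept)`
#' rounded to the workload quantum. The ramp-like transition of the physical
#' protocol is modelled as an ordinary step boundary.
#'
#' @param warmup_workload settled warm-up workload.
#' @param warmup_lactate end-of-warm-up measured lactate (kept in the
#'   signature for alternative, lactate-aware mappings; unused by the default
#'   linear mapping).
#' @param config a [protocol_config()].
#' @return the first fine-adaptation workload.
#' @export
threshold_adaptation <- function(warmup_workload, warmup_lactate = NULL,
                                 config = protocol_config()) {
  inc <- max(config$quantum,
             config$ta_slope * warmup_workload + config$ta_intercept)
  quantize_workload(warmup_workload + inc, config$quantum)
}

#' Fine threshold adaptation decision
#'
#' Rule table on the lactate delta of the previous step: below `fta_low` the
#' big increment, between the band edges the small increment, above `fta_high`
#' hold the workload pending threshold-criterion evaluation.
#'
#' @param history step series so far (needs at least 2 rows with lactate).
#' @param config a [protocol_config()].
#' @return list with `action` (`"increase"` or `"hold"`) and `increment`
#'   (workload units, 0 for hold).
#' @export
next_workload_fta <- function(history, config = protocol_config()) {
  s <- as_step_series(history)
  n <- length(s$lactate)
  d <- if (n < 2) 0 else la_round(s$lactate[n] - s$lactate[n - 1])
  if (exceeds(d, config$fta_high)) {
    list(action = "hold", increment = 0, delta = d)
  } else if (d >= config$fta_low - 1e-9) {
    list(action = "increase", increment = config$increment_small, delta = d)
  } else {
    list(action = "increase", increment = config$increment_big, delta = d)
  }
}

#' Overshoot correction
#'
#' When the first step after the threshold adaptation already shows a lactate
#' delta above `overshoot_cutoff` or an absolute lactate above
#' `overshoot_lactate`, the workload is reduced by `overshoot_quanta` workload
#' quanta and the session continues (flagged `corrected_overshoot`).
#'
#' @param history step series; the last row is the overshooting step.
#' @param config a [protocol_config()].
#' @return the corrected workload.
#' @export
handle_overshoot <- function(history, config = protocol_config()) {
  s <- as_step_series(history)
  quantize_workload(s$workload[length(s$workload)] -
                      config$overshoot_quanta * config$quantum, config$quantum)
}

is_overshoot <- function(delta, lactate, config) {
  exceeds(delta, config$overshoot_cutoff) ||
    exceeds(lactate, config$overshoot_lactate)
}

# One protocol step: advance physiology, sample the analyzer, append the row.
session_step <- function(env, workload, phase, decision) {
  env$state <- advance_step(env$subject, env$state, workload,
                            env$config$step_duration)
  la <- measure_lactate(env$state$current_true_lactate, env$model)
  env$steps <- rbind(env$steps, data.frame(
    index = nrow(env$steps),
    phase = phase,
    workload = workload,
    duration = env$config$step_duration,
    lactate = round(la, 2),
    hr = round(env$state$current_hr, 1),
    rpe = round(rpe_response(env$subject, workload), 1),
    decision = decision,
    timestamp = round(env$state$elapsed_time + env$model$measurement_delay, 2),
    stringsAsFactors = FALSE
  ))
  invisible(la)
}

last_delta <- function(steps) {
  n <- nrow(steps)
  if (n < 2) 0 else la_round(steps$lactate[n] - steps$lactate[n - 1])
}

#' Verify the MLSS workload after a threshold criterion fired
#'
#' Prescribes `lt_workload - verification_reduction` for one step; if the
#' lactate delta over that step is at most `verification_tolerance` the
#' session is complete and the reduced workload is the MLSS workload estimate.
#' Otherwise one further reduction is attempted; a second failure invalidates
#' the session. Used internally by [run_ilt_test()]; exposed for replay and
#' testing of the verification branch in isolation.
#'
#' @param env internal session environment (subject, state, config, model,
#'   steps).
#' @param threshold the fired `threshold_result`.
#' @return list with `estimate` (workload or `NA`), `attempts`, `verified`.
#' @keywords internal
verify_mlss_live <- function(env, threshold) {
  w <- threshold$lt_workload
  for (attempt in seq_len(env$config$max_verification_attempts)) {
    w <- quantize_workload(w - env$config$verification_reduction,
                           env$config$quantum)
    if (w <= 0) return(list(estimate = NA_real_, attempts = attempt,
                            verified = FALSE))
    session_step(env, w, "verification", "reduce_verify")
    d <- last_delta(env$steps)
    if (!exceeds(d, env$config$verification_tolerance))
      return(list(estimate = w, attempts = attempt, verified = TRUE))
  }
  list(estimate = NA_real_, attempts = env$config$max_verification_attempts,
       verified = FALSE)
}

#' Run one complete adaptive lactate threshold test
#'
#' Executes warm-up, threshold adaptation, the fine-adaptation loop with
#' threshold-criterion classification after every step, and the MLSS
#' verification. Deterministic under `seed`: the same subject, configuration
#' and seed yield a byte-identical session record.
#'
#' @param subject a [subject_profile()].
#' @param config a [protocol_config()] for the subject's modality.
#' @param seed integer seed for the session's measurement-noise stream.
#' @param model a [measurement_model()].
#' @return object of class `ilt_session`: `subject_id`, `config`, `steps`
#'   (data frame), `threshold` (`threshold_result`), `mlss_workload_estimate`,
#'   `outcome` (`"completed"`, `"corrected_overshoot"` or `"invalid"`),
#'   `seed`, `verification_attempts`.
#' @export
run_ilt_test <- function(subject, config = protocol_config(subject$modality),
                         seed = 1, model = measurement_model()) {
  if (config$modality != subject$modality)
    stop_domain("config modality does not match subject modality")
  env <- new.env(parent = emptyenv())
  env$subject <- subject
  env$config <- config
  env$model <- model
  env$state <- physio_state(subject)
  env$steps <- data.frame()

  finish <- function(threshold, estimate, outcome, attempts = 0L) {
    structure(list(
      subject_id = subject$id,
      config = config,
      config_hash = config_hash(unclass(config)),
      steps = env$steps,
      threshold = threshold,
      mlss_workload_estimate = estimate,
      outcome = outcome,
      seed = seed,
      verification_attempts = attempts
    ), class = "ilt_session")
  }

  with_seed(derive_seed(seed, "session", subject$id), {
    wu <- tryCatch(run_warmup(subject, config, model, env$state),
                   iltk_domain_error = function(e) e)
    if (inherits(wu, "error")) {
      env$steps <- data.frame()
      return(finish(tc_none(), NA_real_, "invalid"))
    }
    env$state <- wu$state
    env$steps <- data.frame(
      index = 0L, phase = "warmup", workload = wu$workload,
      duration = wu$duration, lactate = round(wu$lactate, 2),
      hr = round(wu$hr, 1),
      rpe = round(rpe_response(subject, wu$workload), 1),
      decision = "warmup_settled",
      timestamp = round(env$state$elapsed_time + model$measurement_delay, 2),
      stringsAsFactors = FALSE)

    w <- threshold_adaptation(wu$workload, wu$lactate, config)
    session_step(env, w, "adaptation", "threshold_adaptation")

    overshoots <- 0L
    corrected <- FALSE
    hold_streak <- 0L
    classify_from <- 1L  # after an overshoot correction the artifact steps
                         # before it are excluded from criterion evaluation
    threshold <- tc_none()

    for (step_i in seq_len(config$max_steps)) {
      d <- last_delta(env$steps)
      la_now <- env$steps$lactate[nrow(env$steps)]

      # overshoot check applies to the first post-adaptation step and, after
      # a correction, to the step following it
      post_ta <- env$steps$phase[nrow(env$steps)] == "adaptation" ||
        env$steps$decision[nrow(env$steps)] == "overshoot_correction"
      if (post_ta && is_overshoot(d, la_now, config)) {
        overshoots <- overshoots + 1L
        if (overshoots >= 2L) return(finish(tc_none(), NA_real_, "invalid"))
        corrected <- TRUE
        w <- handle_overshoot(env$steps, config)
        session_step(env, w, "fine_adaptation", "overshoot_correction")
        classify_from <- nrow(env$steps)
        next
      }

      threshold <- classify_steps(env$steps[classify_from:nrow(env$steps), ],
                                  tc1_threshold = config$tc1_threshold,
                                  tc2_threshold = config$tc2_threshold,
                                  tc2_window = config$tc2_window,
                                  rise_epsilon = config$rise_epsilon,
                                  tc2a_cap = config$tc2a_cap)
      if (threshold$criterion != "none") break

      decision <- next_workload_fta(env$steps, config)
      if (decision$action == "hold") {
        hold_streak <- hold_streak + 1L
      } else if (hold_streak > 0L && hold_streak < config$tc2_window) {
        # stay in watch mode: a pending delayed-criterion window is only
        # abandoned once it expires without any criterion firing
        decision <- list(action = "hold", increment = 0)
        hold_streak <- hold_streak + 1L
      } else {
        hold_streak <- 0L
      }
      if (decision$action == "increase")
        w <- quantize_workload(w + decision$increment, config$quantum)
      session_step(env, w, "fine_adaptation",
                   if (decision$action == "hold") "hold"
                   else sprintf("increase_%g", decision$increment))
    }

    if (threshold$criterion == "none") {
      # the step taken in the final loop iteration has not been classified yet
      threshold <- classify_steps(env$steps[classify_from:nrow(env$steps), ],
                                  tc1_threshold = config$tc1_threshold,
                                  tc2_threshold = config$tc2_threshold,
                                  tc2_window = config$tc2_window,
                                  rise_epsilon = config$rise_epsilon,
                                  tc2a_cap = config$tc2a_cap)
    }
    if (threshold$criterion == "none")
      return(finish(threshold, NA_real_, "invalid"))

    ver <- verify_mlss_live(env, threshold)
    if (!ver$verified)
      return(finish(threshold, NA_real_, "invalid", ver$attempts))

    if (config$exhaustion_extension) {
      session_step(env, quantize_workload(
        threshold$lt_workload + config$increment_small, config$quantum),
        "post", "exhaustion_extension")
    }
    finish(threshold, ver$estimate,
           if (corrected) "corrected_overshoot" else "completed", ver$attempts)
  })
}

#' @export
print.ilt_session <- function(x, ...) {
  unit <- if (x$config$modality == "running") "m/s" else "W"
  cat(sprintf("<ilt_session %s> %s, %d steps, criterion %s, MLSS estimate %s %s\n",
              x$subject_id, x$outcome, nrow(x$steps), x$threshold$criterion,
              if (is.na(x$mlss_workload_estimate)) "NA"
              else sprintf("%.2f", x$mlss_workload_estimate), unit))
  invisible(x)
}
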