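# Study harnesses replicating the three experimental designs on simulated
# cohorts: test-retest reliability, increment-size effect on the lactate rise
# at the threshold, and validity against a 10-km constant velocity test.

#' 10-km constant velocity test (CVT)
#'
#' Five 2-km segments starting 0.2 m/s below the previously assessed lactate
#' threshold velocity. After the second and fourth segment, if blood lactate
#' was constant (absolute delta at most `tolerance`) over the two consecutive
#' segments, the velocity is increased by 0.1 m/s. Returns the highest
#' velocity sustained with constant lactate.
#'
#' @param subject a [subject_profile()] (running).
#' @param lt_velocity lactate threshold velocity from a prior adaptive test,
#'   m/s.
#' @param config a running [protocol_config()] (supplies the steadiness
#'   `verification_tolerance` and workload quantum).
#' @param seed integer seed for the measurement stream.
#' @param model a [measurement_model()].
#' @param start_offset m/s below `lt_velocity` to start at (0.2).
#' @param escalation velocity escalation per accepted pair, m/s (0.1).
#' @param n_segments number of 2-km segments (5).
#' @param segment_m segment length, metres (2000).
#' @return list with `final_velocity` (m/s), `segments` (data frame),
#'   `non_steady` (lactate already rising at the initial velocity).
#' @export
run_cvt <- function(subject, lt_velocity,
                    config = protocol_config("running"), seed = 1,
                    model = measurement_model(),
                    start_offset = 0.2, escalation = 0.1,
                    n_segments = 5, segment_m = 2000) {
  if (subject$modality != "running")
    stop_domain("the constant velocity test is a running protocol")
  if (lt_velocity <= start_offset) stop_domain("lt_velocity too low")
  with_seed(derive_seed(seed, "cvt", subject$id), {
    v <- quantize_workload(lt_velocity - start_offset, config$quantum)
    state <- physio_state(subject)
    seg <- data.frame()
    la_prev <- NA_real_
    sustained <- v
    non_steady <- FALSE
    for (k in seq_len(n_segments)) {
      dur <- segment_m / v / 60
      state <- advance_step(subject, state, v, dur)
      la <- measure_lactate(state$current_true_lactate, model)
      d <- if (is.na(la_prev)) NA_real_ else la_round(la - la_prev)
      seg <- rbind(seg, data.frame(segment = k, velocity = v,
                                   duration_min = round(dur, 2),
                                   lactate_mM = round(la, 2),
                                   delta_mM = d))
      constant <- !is.na(d) && abs(d) <= config$verification_tolerance + 1e-9
      if (k %% 2 == 0 || k == n_segments) {
        if (constant) {
          sustained <- v
          if (k < n_segments) v <- quantize_workload(v + escalation,
                                                     config$quantum)
        } else if (k == 2 && d > 0) {
          non_steady <- TRUE
        }
      }
      la_prev <- la
    }
    list(final_velocity = sustained, segments = seg, non_steady = non_steady)
  })
}

study_result <- function(design, table, summary, seed) {
  structure(list(design = design, table = table, summary = summary,
                 seed = seed), class = "ilt_study")
}

#' @export
print.ilt_study <- function(x, ...) {
  cat(sprintf("<ilt_study: %s> n = %d\n", x$design, nrow(x$table)))
  str(x$summary, give.attr = FALSE)
  invisible(x)
}

#' Day-to-day (test-retest) reliability of the MLSS workload estimate
#'
#' Runs two adaptive threshold tests per subject with independent
#' measurement-noise streams and summarizes the paired estimates: mean signed
#' and absolute day-to-day difference and the Pearson correlation. Invalid
#' sessions are excluded and counted.
#'
#' @param cohort an `ilt_cohort` (>= 2 subjects; the reliability design used
#'   >= 10).
#' @param config a [protocol_config()].
#' @param seed root seed; day-1 and day-2 streams are derived from it.
#' @param model a [measurement_model()].
#' @return an `ilt_study` with per-subject paired estimates and summary
#'   statistics (`r` is `NA` with `degenerate = TRUE` when the estimates have
#'   zero variance).
#' @export
run_reliability_study <- function(cohort, config = NULL, seed = 1,
                                  model = measurement_model()) {
  if (length(cohort) < 2) stop_domain("need at least 2 subjects")
  config <- config %||% protocol_config(cohort[[1]]$modality)
  rows <- lapply(cohort, function(s) {
    s1 <- run_ilt_test(s, config, seed = derive_seed(seed, s$id, "day1"),
                       model = model)
    s2 <- run_ilt_test(s, config, seed = derive_seed(seed, s$id, "day2"),
                       model = model)
    data.frame(subject_id = s$id, true_mlss = s$mlss_workload,
               d1 = s1$mlss_workload_estimate, d2 = s2$mlss_workload_estimate,
               outcome1 = s1$outcome, outcome2 = s2$outcome,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  ok <- !is.na(tab$d1) & !is.na(tab$d2)
  paired <- tab[ok, ]
  degenerate <- nrow(paired) < 2 || stats::sd(paired$d1) == 0 ||
    stats::sd(paired$d2) == 0
  r <- if (degenerate) {
    if (nrow(paired) >= 2 && all(paired$d1 == paired$d2)) 1 else NA_real_
  } else stats::cor(paired$d1, paired$d2)
  summary <- list(
    n = nrow(paired), n_excluded = sum(!ok),
    mean_d1 = mean(paired$d1), mean_d2 = mean(paired$d2),
    mean_diff = mean(paired$d1 - paired$d2),
    mean_abs_diff = mean(abs(paired$d1 - paired$d2)),
    pearson_r = r, degenerate = degenerate
  )
  study_result("reliability", tab, summary, seed)
}

# Brown-Forsythe variant of Levene's test for two groups: t-test on absolute
# deviations from the group medians.
levene_p <- function(x, y) {
  zx <- abs(x - stats::median(x)); zy <- abs(y - stats::median(y))
  if (stats::sd(c(zx, zy)) == 0) return(1)
  stats::t.test(zx, zy, var.equal = TRUE)$p.value
}

#' Two-group comparison with assumption gating
#'
#' Student's two-tailed t-test when Shapiro-Wilk normality (both groups) and
#' Brown-Forsythe variance homogeneity hold at `alpha`; otherwise the
#' Mann-Whitney U test.
#'
#' @param x,y numeric samples.
#' @param alpha gate level (0.05).
#' @return list with `method`, `statistic`, `p_value`, `normality_p`,
#'   `variance_p`.
#' @export
two_group_test <- function(x, y, alpha = 0.05) {
  norm_p <- suppressWarnings(min(stats::shapiro.test(x)$p.value,
                                 stats::shapiro.test(y)$p.value))
  var_p <- levene_p(x, y)
  if (norm_p > alpha && var_p > alpha) {
    ht <- stats::t.test(x, y, var.equal = TRUE)
    list(method = "t", statistic = unname(ht$statistic),
         p_value = ht$p.value, normality_p = norm_p, variance_p = var_p)
  } else {
    ht <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE))
    list(method = "mann-whitney", statistic = unname(ht$statistic),
         p_value = ht$p.value, normality_p = norm_p, variance_p = var_p)
  }
}

#' Increment-size effect on the lactate rise at the threshold
#'
#' Re-runs the cohort once per increment size with the fine-adaptation
#' increments forced to that size, so the final increment at the threshold has
#' the requested magnitude. Only TC1 sessions enter the analysis (the steep
#' rise directly after an increment). Reports group means with standard errors
#' and all pairwise two-group tests.
#'
#' @param cohort an `ilt_cohort`.
#' @param increments increment sizes; defaults to 0.1/0.15/0.3 m/s for
#'   running, 7/10/15 W for cycling.
#' @param config a [protocol_config()].
#' @param seed root seed.
#' @param model a [measurement_model()].
#' @return an `ilt_study`; groups with fewer than 2 TC1 sessions are dropped
#'   (and listed in `summary$dropped`).
#' @export
run_increment_study <- function(cohort, increments = NULL, config = NULL,
                                seed = 1, model = measurement_model()) {
  modality <- cohort[[1]]$modality
  config <- config %||% protocol_config(modality)
  increments <- increments %||%
    (if (modality == "running") c(0.1, 0.15, 0.3) else c(7, 10, 15))
  rows <- list()
  for (inc in increments) {
    cfg <- config
    cfg$increment_big <- inc
    cfg$increment_small <- inc
    for (s in cohort) {
      ses <- run_ilt_test(s, cfg, seed = derive_seed(seed, "inc", inc, s$id),
                          model = model)
      if (ses$threshold$criterion == "TC1") {
        rows[[length(rows) + 1]] <- data.frame(
          increment = inc, subject_id = s$id,
          delta_lactate = ses$threshold$delta_lactate,
          lt_workload = ses$threshold$lt_workload,
          outcome = ses$outcome, stringsAsFactors = FALSE)
      }
    }
  }
  tab <- do.call(rbind, rows)
  counts <- base::table(factor(tab$increment, levels = increments))
  keep <- increments[counts[as.character(increments)] >= 2]
  dropped <- setdiff(increments, keep)
  groups <- lapply(keep, function(i) tab$delta_lactate[tab$increment == i])
  names(groups) <- as.character(keep)
  gm <- data.frame(
    increment = keep,
    n = vapply(groups, length, integer(1)),
    mean_delta = vapply(groups, mean, numeric(1)),
    se_delta = vapply(groups, function(g) stats::sd(g) / sqrt(length(g)),
                      numeric(1))
  )
  tests <- list()
  if (length(keep) >= 2) {
    for (a in seq_along(keep)[-length(keep)]) for (b in seq.int(a + 1, length(keep))) {
      key <- paste(keep[a], "vs", keep[b])
      tests[[key]] <- two_group_test(groups[[a]], groups[[b]])
    }
  }
  study_result("increment", tab,
               list(group_means = gm, tests = tests, dropped = dropped),
               seed)
}

#' Validity of the adaptive test against the constant velocity test
#'
#' Each subject completes an adaptive threshold test and then a 10-km constant
#' velocity test seeded from their threshold velocity. Reports paired
#' velocities (MLSS estimate vs final CVT velocity), mean difference and the
#' Pearson correlation.
#'
#' @param cohort a running `ilt_cohort`.
#' @param config a running [protocol_config()].
#' @param seed root seed.
#' @param model a [measurement_model()].
#' @return an `ilt_study`; `summary$small_n` flags n < 10.
#' @export
run_validity_study <- function(cohort, config = NULL, seed = 1,
                               model = measurement_model()) {
  config <- config %||% protocol_config(cohort[[1]]$modality)
  rows <- lapply(cohort, function(s) {
    ilt <- run_ilt_test(s, config, seed = derive_seed(seed, s$id, "ilt"),
                        model = model)
    if (is.na(ilt$mlss_workload_estimate))
      return(data.frame(subject_id = s$id, true_mlss = s$mlss_workload,
                        ilt = NA_real_, cvt = NA_real_, non_steady = NA,
                        stringsAsFactors = FALSE))
    cvt <- run_cvt(s, ilt$threshold$lt_workload, config,
                   seed = derive_seed(seed, s$id, "cvt"), model = model)
    data.frame(subject_id = s$id, true_mlss = s$mlss_workload,
               ilt = ilt$mlss_workload_estimate,
               cvt = cvt$final_velocity, non_steady = cvt$non_steady,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  ok <- !is.na(tab$ilt) & !is.na(tab$cvt)
  paired <- tab[ok, ]
  degenerate <- nrow(paired) < 2 || stats::sd(paired$ilt) == 0 ||
    stats::sd(paired$cvt) == 0
  r <- if (degenerate) NA_real_ else stats::cor(paired$ilt, paired$cvt)
  summary <- list(
    n = nrow(paired), n_excluded = sum(!ok),
    mean_ilt = mean(paired$ilt), mean_cvt = mean(paired$cvt),
    mean_diff = mean(paired$ilt - paired$cvt),
    mean_abs_diff = mean(abs(paired$ilt - paired$cvt)),
    pearson_r = r, degenerate = degenerate, small_n = nrow(paired) < 10
  )
  study_result("cvt_validity", tab, summary, seed)
}
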