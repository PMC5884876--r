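---
title: "Adaptive lactate threshold testing: model, protocol and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive lactate threshold testing: model, protocol and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iltk)
```

## The problem

The maximal lactate steady state workload (MLSS~W~) is the highest constant
workload at which arterial blood lactate does not drift upward over time, and
the lactate threshold (LT) is the workload at which a minimal further
increment produces a steep lactate rise. Classical MLSS determination needs
several constant-load sessions on separate days. The adaptive step test
implemented here compresses this into a single session: small, lactate-guided
workload adjustments walk the athlete up to the LT, a threshold criterion
fires on the lactate kinetics, and a single small workload reduction verifies
that the accumulation stops — the reduced workload is the MLSS~W~ estimate.

`iltk` provides (i) a virtual-subject simulator of lactate/heart-rate/RPE
responses, (ii) pure detectors for the threshold criteria, (iii) the
closed-loop protocol controller, (iv) study harnesses (test-retest
reliability, increment-size effect, constant-velocity validation), and (v)
CSV/JSON session I/O with a small CLI. Everything is seeded and
reproducible; no real data are required anywhere.

## The subject model

No published lactate production/clearance equations are available at the
granularity this protocol needs, so the simulator uses the *simplest* model
that reproduces every behaviour the protocol must cope with:

* **Below MLSS~W~** true lactate relaxes first-order, with time constant
  $\tau$ (min), toward a workload-linear steady state
  $L_\infty(w) = L_0 + g\,w$, where $L_0$ is resting lactate (mM) and $g$ the
  steady-state slope (mM per workload unit). This yields sub-threshold steady
  states and small, transient inter-step deltas.
* **Above MLSS~W~** there is no steady state: lactate relaxes *upward*
  toward the extrapolated line if below it, never decays while the workload
  stays supra-threshold (clearance is saturated — a "ratchet"), and
  accumulates $r\,(w - w_{MLSS})\cdot d/4$ mM per step of duration $d$
  minutes, with rate $r$ (mM per 4-min step per workload unit of overshoot).
* **Delayed accumulation.** A subject trait `accumulation_lag_steps`
  (0–7) attenuates the accumulation by `lag_attenuation` (default 0.3)
  during the first lag steps at a constant supra-threshold workload. This
  produces the delayed threshold appearance one-to-eight steps after an
  increment. We deliberately use an *attenuated* rather than a zero response
  during the lag: a perfectly flat lag response would be invisible to any
  lactate-guided controller, which would keep incrementing (resetting the
  lag) and the delayed criterion could never fire in closed loop. The slow
  per-step drift that sums past the criterion is also what recorded
  delayed-threshold sessions actually look like.
* **Heart rate** relaxes first-order toward $HR_{rest} + k\,w$; **RPE** is
  linear in workload, anchored at 5 of 10 at MLSS~W~ (the effort sustainable
  for 60 min) and saturating at 10.
* **The analyzer** multiplies true lactate by $(1+\varepsilon)$,
  $\varepsilon \sim N(0,\,cv)$ with $cv = 3\%$, truncated at zero. The ~15 s
  sampling stop and the 60 s analysis time are modelled as no-ops on the
  4-min dynamics and only affect log timestamps.

### Default cohort (the stated world)

`default_parameter_ranges()` draws subjects uniformly from ranges chosen
once, for physiological plausibility, and not revisited:

| parameter | running | cycling | rationale |
|---|---|---|---|
| MLSS workload | 3.0–4.8 m/s | 150–350 W | recreational-to-elite span |
| resting lactate | 1.0–1.4 mM | same | normal resting values |
| steady-state slope | 0.30–0.375 | 0.006–0.009 | implied lactate at MLSS in 1.9–3.2 mM, inside the observed 1.9–5 mM threshold window |
| supra rate | 10–16 | 0.07–0.16 | a 0.1–0.15 m/s (7–10 W) overshoot yields a 0.5–2.4 mM per-step rise |
| lag steps | 0–7 uniform | same | produces both immediate and delayed threshold types |
| HR at MLSS | 165–178 bpm | same | with resting HR 58–70 and age 28–45, the warm-up target (170 − age) maps to 51–79% of MLSS |

`hr_gain` is sampled indirectly through *HR at MLSS* because resting HR, HR
gain and MLSS workload are physiologically coupled; independent uniform
draws on the gain itself can place the warm-up above the threshold, which no
real warm-up prescription would do. MLSS workload is snapped to the workload
quantum (0.05 m/s / 1 W): the quantity is operationally defined only at the
protocol's resolution.

## Threshold criteria

All lactate deltas are rounded to 0.01 mM (analyzer display resolution)
before strict comparisons, so float dust can never decide a threshold.
A series is decomposed into *windows* — maximal runs of constant workload —
and within each window, in precedence order:

* **TC1** — lactate in the step directly after a workload increment exceeds
  the last pre-increment step by *more than* 0.5 mM.
* **TC2** — cumulative rise over the window's first step exceeds 0.4 mM at
  one of the following 1–8 constant-workload steps. The window restarts at
  every workload change (the behaviour of a window across a mid-series
  reduction is not specified anywhere; restarting is the conservative
  choice).
* **TC2a** — at least three consecutive steps each rising by more than
  `rise_epsilon` (0.1 mM) while the episode's cumulative rise stays at or
  below 0.5 mM, *and* TC2 never fires in that window. TC2 takes precedence
  within a window: a creep that sums past the TC2 criterion is a delayed
  threshold, not a sub-criterion one. Note that live (sequential)
  classification can stop at a TC2a that a longer recording would have
  upgraded to TC2; this is inherent to any stopping rule.

The earliest firing window decides. The detectors are pure functions usable
retrospectively on any recorded log (`classify_steps()`, `detect_tc1()`,
`detect_tc2()`, `detect_tc2a()`), and the whole classifier is checked
exhaustively against an independent brute-force implementation on a 0.1 mM
grid plus 10^4 random series.

## The controller

1. **Warm-up** — a proportional feedback loop (0.25-min ticks, ramp-limited
   as a real belt/resistance controller is) holds heart rate at 170 − age;
   settled means within 2 bpm for a sustained interval, tightened so the
   implied workload error is below half a quantum. Degenerate targets (at or
   below resting HR) are rejected.
2. **Threshold adaptation** — the first increment is
   `max(quantum, ta_slope·w + ta_intercept)`; the published protocol uses an
   unpublished pilot-data regression here, so the mapping is configuration
   with defaults (slope 0.10, intercept 0.05 m/s / 5 W) placing the first
   workload below the cohort's MLSS in well over 80% of subjects.
3. **Fine adaptation** — band table on the previous step's delta:
   `< 0.2 mM` → +0.15 m/s (+10 W); `0.2–0.4 mM` → +0.1 m/s (+7 W);
   `> 0.4 mM` → hold, pending criterion evaluation. Once a hold is entered
   the controller stays at constant workload ("watch mode") until a
   criterion fires or the 8-step TC2 window expires — the printed band table
   alone would abandon a pending delayed-threshold window after one quiet
   step, which would make the delayed criterion unreachable.
4. **Overshoot correction** — if the first adapted step rises by more than
   1.0 mM or lactate exceeds 5 mM (the upper threshold-lactate bound), the
   workload drops by two quanta, the session is flagged
   `corrected_overshoot`, and criterion evaluation restarts at the corrected
   step (the artifact jump itself must not fire TC1). A second consecutive
   overshoot invalidates the session.
5. **Verification** — after a criterion fires, the workload is reduced by
   0.1 m/s (7 W); if the next step's delta is at most 0.2 mM the session is
   complete and the reduced workload is the MLSS~W~ estimate; otherwise one
   further reduction is attempted, and a second failure invalidates the
   session. The 0.2 mM tolerance quantifies the qualitative "accumulation
   stopped": twice the analyzer resolution scale and safely below the
   0.4 mM criterion. On the second-reduction path the estimate is the
   workload of the step that actually verified (threshold workload minus two
   reductions).

Sessions are deterministic under a seed (byte-identical records), and the
root seed is split into named streams (cohort, per-session measurement,
study replicates) so re-running one session never perturbs another.

## Numerical choices

* Workload quantum 0.05 m/s / 1 W; every prescribed workload is a multiple.
* Delta comparisons after rounding to 0.01 mM; strict inequalities at
  0.5 / 0.4 mM ("more than"), inclusive band edges in the fine-adaptation
  table.
* First-order steps use the exact exponential update; the test suite checks
  it against an independent RK4 integration to 10^-4 mM.
* Ties in criterion precedence are resolved TC1 > TC2 > TC2a within a
  window, earliest window first.

## What the studies establish — and what they do not

The three harnesses re-create study *designs*, not published values: the
published headline numbers come from 426 real human tests. On the default
simulated cohort the package demonstrates the qualitative anchors — day-to-day
reliability r ≥ 0.95 with mean |d1 − d2| below one increment, constant
velocity test agreement within 0.2 m/s with r ≥ 0.95, and a lactate rise at
the threshold that grows strictly with the forced increment size with the
0.1-vs-0.3 m/s comparison significant at 5%. The increment analysis uses
TC1 sessions only and gates Student's t against Mann-Whitney U via
Shapiro-Wilk and a Brown-Forsythe variance check, as the original analysis
workflow did.

The simulator does **not** model: within-subject day-to-day physiological
drift (only analyzer noise and protocol path vary between repeated sessions;
whether drift should be added is an open question), mechanistic muscle-fiber
or transporter kinetics, VO2 or catecholamine responses, exhaustion beyond a
monotone lactate rise, race pacing (the half-marathon field test is out of
scope; the constant velocity test is the validity endpoint), or real-time
hardware control. A green test therefore establishes protocol-logic
correctness and statistical behaviour under the stated noise model — not
physiological fidelity beyond the reproduced phenomena.

## Worked example

```{r}
subject <- subject_profile(
  id = "demo", age = 30, modality = "running", mlss_workload = 4.0,
  baseline_lactate = 1.2, sub_threshold_gain = 0.35,
  supra_threshold_rate = 12, lactate_time_constant = 2,
  accumulation_lag_steps = 0L
)
session <- run_ilt_test(subject, protocol_config("running"), seed = 1)
session
session$steps[, c("phase", "workload", "lactate", "decision")]
```

The staircase climbs in 0.15 m/s steps while deltas are small, crosses the
true MLSS (4.0 m/s), the steep-rise criterion fires, and verification walks
the workload back down until the accumulation stops.
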