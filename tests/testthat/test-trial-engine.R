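# Event-driven trial engine: event-time model, allocation, triggers,
# futility decisions, and whole-trial behaviour.

test_that("event times are exponential with the hazard-ratio-scaled median", {
  set.seed(11)
  x <- draw_event_times(1e6, 24, 1.0)
  expect_equal(median(x), 24, tolerance = 0.1 / 24)
  y <- draw_event_times(1e6, 24, 0.75)
  expect_equal(median(y), 32, tolerance = 0.15 / 32)
  expect_identical(draw_event_times(0, 24, 1), numeric(0))
  expect_error(draw_event_times(10, -1, 1), "positive")
  expect_error(draw_event_times(10, 24, 0), "positive")
})

test_that("interim decisions stop at or above the stage threshold", {
  sch <- analysis_schedule()
  expect_identical(interim_decision(1.05, 1, sch), "stop_futility")
  expect_identical(interim_decision(0.80, 2, sch), "continue")
  expect_identical(interim_decision(0.89, 3, sch), "stop_futility")  # tie
  expect_identical(interim_decision(0.9199, 2, sch), "continue")
  expect_error(interim_decision(1, 4, sch), "stage")
})

test_that("analysis schedules validate monotonicity", {
  expect_error(analysis_schedule(c(100, 100, 200), c(1, 0.9, 0.8), 400),
               "increasing")
  expect_error(analysis_schedule(c(100, 200, 300), c(0.8, 0.9, 1), 400),
               "non-increasing")
  expect_error(analysis_schedule(c(100, 200), c(1, 0.9, 0.8), 400), "length")
})

test_that("concurrent-control event counts respect the arm's window", {
  expect_equal(concurrent_control_count(numeric(0), numeric(0), 0, 1), 0)
  # three controls in-window, FFS events at calendar 1, 2, 9.9; t = 2.5
  expect_equal(concurrent_control_count(c(0.5, 0.8, 1.2), c(1, 2, 9.9),
                                        0, 2.5), 2)
  # enrollment outside the window is excluded
  expect_equal(concurrent_control_count(c(0.5, 3.0), c(1, 3.5), 0, 4,
                                        window_end = 2), 1)
  expect_error(concurrent_control_count(1, 2, 5, 4), "precedes")
})

test_that("trial design constructors enforce their invariants", {
  expect_error(arm_spec("a", hr_ffs = 0), "positive")
  expect_error(arm_spec("a", cap = 0), "positive")
  expect_error(trial_design("two_group", arms = list()), "at least one")
  expect_error(trial_design("two_group",
                            arms = list(arm_spec("a", entry_time = 1))),
               "time 0")
  expect_error(
    trial_design("two_group",
                 arms = list(arm_spec("a"), arm_spec("b", entry_time = 2))),
    "platform")
  expect_error(trial_design("two_group", arms = list(arm_spec("a")),
                            control_median_ffs = 30, control_median_os = 24),
               "cannot exceed")
  d <- trial_design("platform", arms = lapply(1:2, function(i)
    arm_spec(paste0("a", i))))
  expect_equal(d$n_sites, 120L)
  expect_equal(d$control_weight_initial, 2)
})

test_that("a trial simulation is deterministic under a fixed seed", {
  d <- fast_two_group()
  set.seed(5); a <- simulate_trial(d)
  set.seed(5); b <- simulate_trial(d)
  expect_identical(a, b)
  set.seed(6); c_ <- simulate_trial(d)
  expect_false(identical(a$end_time, c_$end_time))
})

test_that("analysis times are strictly ordered within each arm", {
  d <- fast_two_group(hr = 0.5)  # usually survives to the final
  set.seed(8)
  for (i in 1:20) {
    out <- simulate_trial(d)
    an <- out$analyses
    # stage 0 (final) sorts last
    ord <- order(ifelse(an$stage == 0, 99, an$stage))
    expect_true(all(diff(an$time[ord]) > 0))
    expect_lte(nrow(an), 4)
  }
})

test_that("per-patient failure-free survival never exceeds survival", {
  set.seed(9)
  out <- simulate_trial(fast_two_group(), keep_patients = TRUE)
  expect_true(all(out$patients$ffs_cal <= out$patients$os_cal))
  expect_true(all(out$patients$ffs_cal >= out$patients$enroll_time))
})

test_that("allocation follows the weights, including the 2:1 control", {
  # 5 arms + control at weight 2: control share 2/7
  arms <- lapply(1:5, function(i) arm_spec(paste0("a", i), cap = 4000L))
  d <- trial_design("multigroup", arms = arms, n_sites = 50L,
                    accrual_per_site_year = 20,
                    control_median_ffs = 12, control_median_os = 24,
                    schedule = analysis_schedule(c(50L), c(Inf), 100L))
  set.seed(10)
  out <- simulate_trial(d, keep_patients = TRUE)
  n <- nrow(out$patients)
  expect_equal(mean(out$patients$group == "control"), 2 / 7,
               tolerance = 0.06)
  # arrivals are deterministic at the aggregate rate: 1000/year
  u <- sort(out$patients$enroll_time)
  expect_equal(diff(u)[1:100], rep(1 / 1000, 100), tolerance = 1e-6)
})

test_that("two active groups at equal weights split enrollment evenly", {
  d <- fast_two_group(cap = 300L, triggers = c(200L), thresholds = c(Inf),
                      final = 250L)
  set.seed(12)
  out <- simulate_trial(d, keep_patients = TRUE)
  expect_equal(mean(out$patients$group == "control"), 0.5, tolerance = 0.05)
})

test_that("arms never exceed their caps and stop randomizing when dropped", {
  d <- fast_two_group(hr = 2.0)  # stops for futility almost surely
  set.seed(13)
  out <- simulate_trial(d, keep_patients = TRUE)
  expect_true(all(out$arms$n_enrolled <= 20L))
  expect_match(out$arms$stop_reason, "futility")
  expect_false(out$arms$final_performed)
  # no patient of the dropped arm enrolled after its stop time
  p <- out$patients[out$patients$group == "arm_1", ]
  expect_true(all(p$enroll_time <= out$arms$stop_time + 1e-9))
})

test_that("forcing stage-1 futility reduces enrollment versus no interims", {
  d_stop <- fast_two_group(triggers = c(3L, 5L, 7L),
                           thresholds = c(0, 0, 0), final = 8L)
  d_none <- fast_two_group(triggers = c(3L, 5L, 7L),
                           thresholds = c(Inf, Inf, Inf), final = 8L)
  set.seed(14); a <- simulate_trial(d_stop)
  set.seed(14); b <- simulate_trial(d_none)
  expect_lt(a$total_enrolled, b$total_enrolled)
  expect_identical(a$arms$stop_reason, "futility_stage_1")
})

test_that("stage-1 stops are calibrated to one half under the null", {
  # with HR = 1 and a futility threshold of 1.0, the estimated HR exceeds
  # the threshold about half the time
  d <- calibration_design(hr = 1.0, threshold = 1.0)
  set.seed(15)
  stops <- vapply(1:2500, function(i) {
    out <- suppressWarnings(simulate_trial(d))
    identical(out$arms$stop_reason, "futility_stage_1")
  }, logical(1))
  expect_equal(mean(stops), 0.5, tolerance = 0.03 / 0.5)
})

test_that("unreachable triggers force a flagged final analysis", {
  # final trigger far beyond what 20 + 20 patients can produce
  d <- fast_two_group(triggers = c(3L), thresholds = c(Inf), final = 400L)
  set.seed(16)
  expect_warning(out <- simulate_trial(d), "forced")
  expect_equal(out$n_forced, 1L)
  expect_true(out$arms$forced)
  expect_true(out$arms$final_performed)
  expect_identical(out$arms$stop_reason, "final_analysis")
})

test_that("platform arms activate at entry time plus the sampled lead", {
  arms <- list(arm_spec("a1", cap = 30L),
               arm_spec("a2", entry_time = 0.5, cap = 30L))
  d <- trial_design("platform", arms = arms, n_sites = 5L,
                    accrual_per_site_year = 40,
                    schedule = analysis_schedule(c(5L), c(Inf), 10L))
  set.seed(17)
  out <- simulate_trial(d, arm_delays = c(0, 6), keep_patients = TRUE)
  expect_equal(out$arms$activation_time[2], 1.0)
  p2 <- out$patients[out$patients$group == "a2", ]
  expect_true(all(p2$enroll_time > 1.0))
  # interim analyses of the added arm happen after its activation
  an2 <- out$analyses[out$analyses$label == "a2", ]
  expect_true(all(an2$time > 1.0))
})

test_that("follow-up exposure tallies are internally consistent", {
  set.seed(18)
  out <- simulate_trial(fast_two_group(), keep_patients = TRUE)
  expect_equal(out$trial_months, out$end_time * 12)
  expect_equal(out$site_months, out$n_sites * out$end_time * 12)
  expect_equal(out$total_enrolled, nrow(out$patients))
  # patient-months bounded by full survival exposure
  full <- sum(out$patients$os_cal - out$patients$enroll_time) * 12
  expect_lte(out$patient_months, full + 1e-9)
  expect_gt(out$patient_months, 0)
})
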