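# Shared test fixtures, all generated in code.

# fast two-group design for engine tests: ~100 patients/year, small event
# triggers, caps 20 per arm
fast_two_group <- function(hr = 0.75, cap = 20L,
                           triggers = c(3L, 5L, 7L),
                           thresholds = c(1.0, 0.92, 0.89),
                           final = 8L) {
  trial_design(
    design_type = "two_group",
    arms = list(arm_spec("arm_1", hr_ffs = hr, hr_os = hr, cap = cap)),
    n_sites = 5L, accrual_per_site_year = 20,
    schedule = analysis_schedule(triggers, thresholds, final)
  )
}

# medium two-group design for calibration checks: one interim at 60
# concurrent-control FFS events
calibration_design <- function(hr = 1.0, threshold = 1.0) {
  trial_design(
    design_type = "two_group",
    arms = list(arm_spec("arm_1", hr_ffs = hr, hr_os = hr, cap = 150L)),
    n_sites = 10L, accrual_per_site_year = 30,
    schedule = analysis_schedule(60L, threshold, 80L)
  )
}

# parameter table with all SDs set to zero: every draw equals the mean
degenerate_table <- function() {
  tab <- default_parameter_table()
  tab$sd <- 0
  tab
}

# log-rank oracle via the survival package (skipped if unavailable)
survdiff_chisq <- function(time, event, group) {
  df <- data.frame(time = time, event = event, group = group)
  fit <- survival::survdiff(survival::Surv(time, event) ~ group, data = df)
  unname(fit$chisq)
}
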