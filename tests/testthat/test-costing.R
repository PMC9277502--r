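# Top-down costing: component arithmetic, conservation, and monotonicity.

means_setup <- function(design_type) {
  tab <- degenerate_table()
  # all SDs zero: draws equal the elicited means exactly
  draw_setup_parameters(tab, design_type)
}

test_that("setup cost is the component sum plus per-site setup", {
  s <- means_setup("platform")
  expect_equal(setup_cost(list(n_sites = 120), s),
               155667 + 172250 + 42500 + 120 * 9440)  # 1,503,217
  s2 <- means_setup("two_group")
  expect_equal(setup_cost(list(n_sites = 50), s2),
               123333 + 151183 + 32500 + 50 * 9440)   # 779,016
  expect_equal(setup_cost(list(n_sites = 0), s2),
               123333 + 151183 + 32500)
  expect_error(setup_cost(list(n_sites = 10), list(costs = c(protocol = 1))),
               "missing components")
})

test_that("setup time runs protocol first, then the longer parallel task", {
  s <- means_setup("platform")
  expect_equal(setup_time(s), (8.78 + max(6.50, 5.40)) / 12)  # 1.273 years
  s2 <- means_setup("two_group")
  expect_equal(setup_time(s2), (3.92 + 3.67) / 12)            # 0.633 years
  s2$times["database"] <- 0
  expect_equal(setup_time(s2), (3.92 + 3.67) / 12)
  expect_equal(setup_time(s2, "sequential"), (3.92 + 3.67 + 0) / 12)
})

test_that("conduct cost is linear in the exposure tallies", {
  shared <- draw_shared_parameters(degenerate_table())
  out <- list(total_enrolled = 100, patient_months = 1200,
              site_months = 240, trial_months = 24)
  expect_equal(conduct_cost(out, shared),
               100 * 1300 + 1200 * 313 + 240 * 5000 + 24 * 2500) # 1,765,600
  zero <- list(total_enrolled = 0, patient_months = 0, site_months = 0,
               trial_months = 0)
  expect_equal(conduct_cost(zero, shared), 0)
  # doubling patient-months adds exactly the follow-up rate times the extra
  out2 <- out
  out2$patient_months <- 2400
  expect_equal(conduct_cost(out2, shared) - conduct_cost(out, shared),
               1200 * 313)
  bad <- out
  bad$patient_months <- -1
  expect_error(conduct_cost(bad, shared), "negative")
})

test_that("analysis cost charges interims and gated finals per arm", {
  shared <- draw_shared_parameters(degenerate_table())
  mk <- function(n_int, final) list(arms = data.frame(
    n_interims_performed = n_int, final_performed = final))
  expect_equal(analysis_cost(mk(3L, TRUE), shared),
               3 * 12883 + 42750)                      # 81,399
  expect_equal(analysis_cost(mk(1L, FALSE), shared), 12883)
  expect_equal(analysis_cost(mk(integer(0), logical(0)), shared), 0)
  # several arms accumulate
  expect_equal(analysis_cost(mk(c(3L, 1L), c(TRUE, FALSE)), shared),
               3 * 12883 + 42750 + 12883)
})

test_that("arm additions cost and delay per added group", {
  tab <- degenerate_table()
  ad <- add_arm_cost_and_delay(5, tab)
  expect_equal(ad$cost, 5 * 75626)                     # 378,130
  expect_equal(ad$delays_months, rep(3, 5))
  none <- add_arm_cost_and_delay(0, tab)
  expect_equal(none$cost, 0)
  expect_length(none$delays_months, 0)
  expect_error(add_arm_cost_and_delay(2, tab, design_type = "two_group"),
               "platform")
  expect_error(add_arm_cost_and_delay(-1, tab), "non-negative")
})

test_that("cost breakdowns conserve the component sum exactly", {
  out <- list(duration = 10)
  cb <- cost_breakdown(out, 1e6, 2e6, 1e5, 4e5, setup_time = 1.2)
  expect_identical(cb$total_cost, 1e6 + 2e6 + 1e5 + 4e5)  # 3.5M
  expect_equal(cb$total_duration, 11.2)
  a <- structure(1e6, iteration = 1)
  b <- structure(2e6, iteration = 2)
  expect_error(cost_breakdown(out, a, b, 0, 0), "different iterations")
  expect_error(cost_breakdown(out, -1, 0, 0, 0), "non-negative")
})

test_that("shared site-setup draws are reused when supplied", {
  tab <- default_parameter_table()
  set.seed(21)
  s <- draw_setup_parameters(tab, "platform", site_setup = 1234)
  expect_equal(unname(s$costs["site_setup"]), 1234)
  set.seed(21)
  s2 <- draw_setup_parameters(tab, "two_group", site_setup = 1234)
  expect_equal(unname(s2$costs["site_setup"]), 1234)
})

test_that("earlier futility never increases conduct cost at matched seeds", {
  shared <- draw_shared_parameters(degenerate_table())
  d_stop <- fast_two_group(thresholds = c(0, 0, 0))
  d_none <- fast_two_group(thresholds = c(Inf, Inf, Inf))
  for (seed in 31:35) {
    set.seed(seed); a <- simulate_trial(d_stop)
    set.seed(seed); b <- simulate_trial(d_none)
    expect_lte(conduct_cost(a, shared), conduct_cost(b, shared))
  }
})

test_that("single-trial setup samples have the expected scale", {
  set.seed(22)
  s <- setup_requirement_samples("platform", 2000)
  # protocol-then-parallel at the elicited means gives 1.273 years before
  # positivity truncation; simulated means sit a little above
  expect_gt(mean(s$setup_time), 1.2)
  expect_lt(mean(s$setup_time), 1.5)
  expect_true(all(s$setup_cost > 0))
  expect_error(setup_requirement_samples("other", 10), "unknown design")
})
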