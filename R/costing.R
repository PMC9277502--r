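# Top-down costing of a simulated trial realization: setup, conduct,
# analysis and (platform-only) arm-addition components, plus setup/total
# time assembly. Unit costs come from sampled elicited parameters; no
# discounting is applied (costs are nominal 2021 US dollars).

#' Sample the setup parameters for one trial
#'
#' Draws the design-type-specific setup costs (protocol development, trial
#' approvals, database development — lognormal), the shared per-site setup
#' cost (lognormal), and the three setup times (normal, months,
#' positive-constrained). The per-site setup cost is a shared parameter:
#' within a Monte-Carlo iteration the same draw applies to every trial in
#' every scenario, so pass it in via `site_setup` (as [run_monte_carlo()]
#' does, from [draw_shared_parameters()]); left `NULL`, a fresh draw is
#' taken.
#'
#' @param table Parameter table ([default_parameter_table()]).
#' @param design_type `"two_group"`, `"multigroup"` or `"platform"`.
#' @param anchor Lognormal anchoring passed to [sample_parameter()].
#' @param site_setup Optional per-site setup cost draw to reuse.
#' @return A list with numeric vectors `costs` (protocol, approvals,
#'   database, site_setup) and `times` (protocol, approvals, database;
#'   months).
#' @export
draw_setup_parameters <- function(table, design_type,
                                  anchor = c("median", "mean"),
                                  site_setup = NULL) {
  anchor <- match.arg(anchor)
  g <- function(name) sample_parameter(param_lookup(table, name, design_type),
                                       1L, anchor)
  if (is.null(site_setup)) site_setup <- g("site_setup")
  list(
    costs = c(protocol = g("protocol_development"),
              approvals = g("trial_approvals"),
              database = g("database_development"),
              site_setup = unname(site_setup)),
    times = c(protocol = g("protocol_development_time"),
              approvals = g("trial_approvals_time"),
              database = g("database_development_time"))
  )
}

#' Sample the shared conduct and analysis unit costs
#'
#' One draw per shared parameter; within a Monte-Carlo iteration the same
#' draws are applied to every trial in every scenario (common random
#' numbers), so scenario differences reflect trial structure rather than
#' unit-cost noise.
#'
#' @inheritParams draw_setup_parameters
#' @return Named list: `site_setup` (per site), `recruitment` (per
#'   patient), `followup` (per patient-month), `site_mgmt` (per
#'   site-month), `db_mgmt` (per trial-month), `interim` and `final` (per
#'   group analysis).
#' @export
draw_shared_parameters <- function(table, anchor = c("median", "mean")) {
  anchor <- match.arg(anchor)
  g <- function(name) sample_parameter(param_lookup(table, name), 1L, anchor)
  list(site_setup = g("site_setup"),
       recruitment = g("recruitment_per_patient"),
       followup = g("monthly_followup_per_patient"),
       site_mgmt = g("monthly_site_management"),
       db_mgmt = g("monthly_database_management"),
       interim = g("interim_analysis_per_group"),
       final = g("final_analysis_per_group"))
}

#' Trial setup cost
#'
#' Protocol development + trial approvals + database development + per-site
#' setup times the number of sites.
#'
#' @param design A [trial_design()] (only `n_sites` is used).
#' @param setup Draws from [draw_setup_parameters()].
#' @return Setup cost in 2021 USD.
#' @export
setup_cost <- function(design, setup) {
  costs <- setup$costs
  needed <- c("protocol", "approvals", "database", "site_setup")
  if (!all(needed %in% names(costs)))
    stop("setup draws are missing components: ",
         paste(setdiff(needed, names(costs)), collapse = ", "), call. = FALSE)
  unname(costs["protocol"] + costs["approvals"] + costs["database"] +
           costs["site_setup"] * design$n_sites)
}

#' Trial setup time
#'
#' Under the default `"protocol_then_parallel"` schedule, protocol
#' development runs first and approvals and database development then run
#' in parallel, so setup time is `protocol + max(approvals, database)`.
#' The `"sequential"` alternative sums all three.
#'
#' @param setup Draws from [draw_setup_parameters()].
#' @param schedule Setup scheduling assumption.
#' @return Setup time in years.
#' @export
setup_time <- function(setup, schedule = c("protocol_then_parallel",
                                           "sequential")) {
  schedule <- match.arg(schedule)
  t <- setup$times
  months <- if (schedule == "protocol_then_parallel") {
    t[["protocol"]] + max(t[["approvals"]], t[["database"]])
  } else {
    t[["protocol"]] + t[["approvals"]] + t[["database"]]
  }
  months / 12
}

#' Trial conduct cost
#'
#' Recruitment per patient times total enrollment, plus monthly follow-up
#' per patient-month, site management per site-month and database
#' management per trial-month of the simulated realization.
#'
#' @param outcome A `trial_outcome` from [simulate_trial()], or any list
#'   with fields `total_enrolled`, `patient_months`, `site_months`,
#'   `trial_months`.
#' @param shared Draws from [draw_shared_parameters()].
#' @return Conduct cost in 2021 USD.
#' @export
conduct_cost <- function(outcome, shared) {
  ex <- c(outcome$total_enrolled, outcome$patient_months,
          outcome$site_months, outcome$trial_months)
  if (any(!is.finite(ex)) || any(ex < 0))
    stop("trial outcome has negative or missing exposure tallies",
         call. = FALSE)
  shared$recruitment * outcome$total_enrolled +
    shared$followup * outcome$patient_months +
    shared$site_mgmt * outcome$site_months +
    shared$db_mgmt * outcome$trial_months
}

#' Trial analysis cost
#'
#' Each intervention arm is charged the per-group interim cost for every
#' interim analysis performed and the per-group final-analysis cost if its
#' final analysis ran (arms stopped for futility are not charged a final).
#' The control group is not charged separately: analyses are pairwise
#' against control.
#'
#' @inheritParams conduct_cost
#' @return Analysis cost in 2021 USD.
#' @export
analysis_cost <- function(outcome, shared) {
  arms <- outcome$arms
  sum(arms$n_interims_performed * shared$interim +
        as.numeric(arms$final_performed) * shared$final)
}

#' Cost and lead time of adding intervention groups to a platform
#'
#' One lognormal cost draw and one positive-normal lead-time draw (months)
#' per added group. The lead times are meant to be fed back to
#' [simulate_trial()] as `arm_delays` for the added arms.
#'
#' @param n_added Number of groups added after initiation.
#' @param table Parameter table.
#' @param design_type Must be `"platform"`; any other design cannot add
#'   groups.
#' @param anchor Lognormal anchoring.
#' @return List with `cost` (total USD), `costs` (per-group draws) and
#'   `delays_months` (per-group lead times).
#' @export
add_arm_cost_and_delay <- function(n_added, table, design_type = "platform",
                                   anchor = c("median", "mean")) {
  anchor <- match.arg(anchor)
  if (design_type != "platform")
    stop("only platform designs can add intervention groups", call. = FALSE)
  if (n_added < 0) stop("`n_added` must be non-negative", call. = FALSE)
  if (n_added == 0L)
    return(list(cost = 0, costs = numeric(0), delays_months = numeric(0)))
  costs <- sample_parameter(param_lookup(table, "add_group_cost", "platform"),
                            n_added, anchor)
  delays <- sample_parameter(param_lookup(table, "add_group_time", "platform"),
                             n_added, anchor)
  list(cost = sum(costs), costs = costs, delays_months = delays)
}

#' Assemble a cost breakdown for one trial realization
#'
#' Totals the four cost components with exact conservation and assembles
#' the trial's total duration as setup time plus the conduct span (trial
#' start to last analysis). Components carrying an `iteration` attribute
#' are checked for consistency.
#'
#' @param outcome A `trial_outcome`.
#' @param setup_cost,conduct_cost,analysis_cost,add_arm_cost Cost
#'   components in USD.
#' @param setup_time Setup time in years.
#' @return A one-row tibble with the components, `total_cost` and
#'   `total_duration`.
#' @export
cost_breakdown <- function(outcome, setup_cost, conduct_cost, analysis_cost,
                           add_arm_cost = 0, setup_time = 0) {
  comp <- list(setup_cost, conduct_cost, analysis_cost, add_arm_cost)
  iters <- unlist(lapply(comp, attr, "iteration"))
  if (length(iters) > 1L && length(unique(iters)) > 1L)
    stop("cost components come from different iterations: ",
         paste(unique(iters), collapse = ", "), call. = FALSE)
  vals <- vapply(comp, as.numeric, numeric(1))
  if (any(vals < 0)) stop("cost components must be non-negative", call. = FALSE)
  tibble::tibble(
    setup_cost = vals[1], conduct_cost = vals[2], analysis_cost = vals[3],
    add_arm_cost = vals[4], total_cost = sum(vals),
    setup_time = as.numeric(setup_time),
    conduct_span = outcome$duration,
    total_duration = as.numeric(setup_time) + outcome$duration
  )
}

#' Monte-Carlo samples of single-trial setup requirements
#'
#' Repeated draws of setup time and setup cost for a single trial of the
#' given design type, using the elicited setup parameters and the default
#' site counts (120/80/50). Used to characterize the setup-requirement
#' distributions by design type.
#'
#' @param design_type `"two_group"`, `"multigroup"` or `"platform"`.
#' @param n Number of draws.
#' @param table Parameter table.
#' @param n_sites Site count (defaults to the design type's standard).
#' @param anchor Lognormal anchoring.
#' @param schedule Setup scheduling assumption (see [setup_time()]).
#' @return A tibble with `n` rows: `setup_time` (years) and `setup_cost`
#'   (USD 2021).
#' @export
setup_requirement_samples <- function(design_type, n = 5000L,
                                      table = default_parameter_table(),
                                      n_sites = NULL,
                                      anchor = c("median", "mean"),
                                      schedule = c("protocol_then_parallel",
                                                   "sequential")) {
  anchor <- match.arg(anchor)
  schedule <- match.arg(schedule)
  if (is.null(n_sites))
    n_sites <- switch(design_type, platform = 120L, multigroup = 80L,
                      two_group = 50L,
                      stop("unknown design type: ", design_type,
                           call. = FALSE))
  design <- list(n_sites = n_sites)
  st <- numeric(n)
  sc <- numeric(n)
  for (i in seq_len(n)) {
    s <- draw_setup_parameters(table, design_type, anchor)
    st[i] <- setup_time(s, schedule)
    sc[i] <- setup_cost(design, s)
  }
  tibble::tibble(setup_time = st, setup_cost = sc)
}
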