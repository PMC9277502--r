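# The three competing programme scenarios for evaluating ten interventions:
#   1. one platform trial (5 initial arms, 5 added later),
#   2. one 6-group trial plus five 2-group trials,
#   3. ten independent 2-group trials.
# Entry offsets of the later interventions are identical across scenarios.

#' Scenario configuration
#'
#' Collects everything the scenario builder needs: intervention labels and
#' entry offsets, per-design-type site counts, accrual rate, caps, control
#' medians, the analysis schedule, and optional per-arm hazard-ratio
#' overrides for each effect case.
#'
#' The default entry offsets for interventions 6-10 (6, 8, 8.5, 11 and 12
#' years) approximate the public arm-entry history of a long-running
#' multi-arm prostate-cancer platform trial and are configurable.
#'
#' @param entry_offsets Years from programme start at which each of the ten
#'   interventions becomes available (first five must be 0).
#' @param n_sites Named vector of site counts per design type.
#' @param accrual_per_site_year Patients per site per year.
#' @param cap Per-arm recruitment cap.
#' @param control_median_ffs,control_median_os Control medians in months.
#' @param schedule An [analysis_schedule()].
#' @param add_arm_lead_months Default platform activation lag in months.
#' @param hr_overrides Optional data frame with columns `arm` (1-10),
#'   `case` (`base`, `best`, `pessimistic`), `hr_ffs`, `hr_os` supplying
#'   published per-arm effect estimates in place of the target defaults.
#' @param n_iterations Default Monte-Carlo iteration count.
#' @return A list of class `scenario_config`.
#' @export
scenario_config <- function(entry_offsets = c(0, 0, 0, 0, 0, 6, 8, 8.5, 11, 12),
                            n_sites = c(platform = 120L, multigroup = 80L,
                                        two_group = 50L),
                            accrual_per_site_year = 500 / 120,
                            cap = 443L,
                            control_median_ffs = 12,
                            control_median_os = 24,
                            schedule = analysis_schedule(),
                            add_arm_lead_months = 3,
                            hr_overrides = NULL,
                            n_iterations = 5000L) {
  if (length(entry_offsets) != 10L)
    stop("the programme evaluates exactly 10 interventions; supply 10 ",
         "entry offsets", call. = FALSE)
  if (any(entry_offsets[1:5] != 0))
    stop("the first five interventions are available at programme start ",
         "(offset 0)", call. = FALSE)
  if (is.unsorted(entry_offsets))
    stop("entry offsets must be non-decreasing", call. = FALSE)
  for (dt in c("platform", "multigroup", "two_group"))
    if (!dt %in% names(n_sites))
      stop("`n_sites` must name platform, multigroup and two_group counts",
           call. = FALSE)
  structure(list(entry_offsets = entry_offsets, n_sites = n_sites,
                 accrual_per_site_year = accrual_per_site_year,
                 cap = as.integer(cap),
                 control_median_ffs = control_median_ffs,
                 control_median_os = control_median_os,
                 schedule = schedule,
                 add_arm_lead_months = add_arm_lead_months,
                 hr_overrides = hr_overrides,
                 n_iterations = as.integer(n_iterations)),
            class = "scenario_config")
}

#' Per-arm hazard ratios under an effect case
#'
#' The base case uses the target effect of HR 0.75 on both FFS and OS for
#' every intervention; the best case doubles the effect (HR 0.5625); the
#' pessimistic case assumes no effect (HR 1.00). Published per-arm
#' estimates, where available, can override these targets through
#' `config$hr_overrides`.
#'
#' @param case `"base"`, `"best"` or `"pessimistic"`.
#' @param config A [scenario_config()].
#' @return A tibble with columns `arm`, `hr_ffs`, `hr_os`.
#' @export
effect_case_table <- function(case = c("base", "best", "pessimistic"),
                              config = scenario_config()) {
  case <- match.arg(case)
  hr <- switch(case, base = 0.75, best = 0.5625, pessimistic = 1.00)
  tab <- tibble::tibble(arm = 1:10, hr_ffs = hr, hr_os = hr)
  ov <- config$hr_overrides
  if (!is.null(ov)) {
    ov <- ov[ov$case == case, , drop = FALSE]
    if (any(ov$hr_ffs <= 0) || any(ov$hr_os <= 0))
      stop("hazard-ratio overrides must be positive", call. = FALSE)
    idx <- match(ov$arm, tab$arm)
    if (anyNA(idx)) stop("hr_overrides reference unknown arms", call. = FALSE)
    tab$hr_ffs[idx] <- ov$hr_ffs
    tab$hr_os[idx] <- ov$hr_os
  }
  tab
}

#' Build one of the three competing scenarios
#'
#' @param id Scenario id: 1 (single platform trial), 2 (one 6-group trial
#'   plus five 2-group trials), 3 (ten 2-group trials).
#' @param effect_case `"base"`, `"best"` or `"pessimistic"`.
#' @param config A [scenario_config()].
#' @return A list of class `scenario_spec` with elements `id`,
#'   `effect_case`, `trials` (list of [trial_design()]s) and
#'   `start_offsets` (years from programme start at which each trial
#'   initiates).
#' @export
build_scenario <- function(id, effect_case = c("base", "best", "pessimistic"),
                           config = scenario_config()) {
  effect_case <- match.arg(effect_case)
  if (!id %in% 1:3) stop("scenario id must be 1, 2 or 3", call. = FALSE)
  eff <- effect_case_table(effect_case, config)
  off <- config$entry_offsets
  mk_arm <- function(i, entry = 0) {
    arm_spec(label = paste0("arm_", i), entry_time = entry,
             hr_ffs = eff$hr_ffs[i], hr_os = eff$hr_os[i],
             cap = config$cap, allocation_weight = 1)
  }
  common <- function(type, arms, cw = NULL) {
    trial_design(design_type = type, arms = arms,
                 n_sites = config$n_sites[[type]],
                 accrual_per_site_year = config$accrual_per_site_year,
                 control_weight_initial = cw,
                 control_median_ffs = config$control_median_ffs,
                 control_median_os = config$control_median_os,
                 schedule = config$schedule,
                 add_arm_lead_months = config$add_arm_lead_months)
  }
  if (id == 1L) {
    arms <- lapply(1:10, function(i) mk_arm(i, entry = off[i]))
    trials <- list(common("platform", arms, cw = 2))
    starts <- 0
  } else if (id == 2L) {
    first <- common("multigroup", lapply(1:5, mk_arm), cw = 2)
    rest <- lapply(6:10, function(i) common("two_group", list(mk_arm(i)),
                                            cw = 1))
    trials <- c(list(first), rest)
    starts <- c(0, off[6:10])
  } else {
    trials <- lapply(1:10, function(i) common("two_group", list(mk_arm(i)),
                                              cw = 1))
    starts <- off
  }
  structure(list(id = id, effect_case = effect_case, trials = trials,
                 start_offsets = starts, config = config),
            class = "scenario_spec")
}

#' Read / write a scenario configuration as YAML
#'
#' Serializes every scalar field of a [scenario_config()]; the analysis
#' schedule is stored as its trigger/threshold vectors and hazard-ratio
#' overrides as a list of records.
#'
#' @param path File path.
#' @return `read_scenario_config()` returns a [scenario_config()];
#'   `write_scenario_config()` returns `path` invisibly.
#' @export
read_scenario_config <- function(path) {
  if (!file.exists(path))
    stop("scenario config not found: ", path, call. = FALSE)
  y <- yaml::read_yaml(path)
  sched <- if (!is.null(y$schedule)) {
    analysis_schedule(
      futility_event_triggers = unlist(y$schedule$futility_event_triggers),
      futility_hr_thresholds = unlist(y$schedule$futility_hr_thresholds),
      final_death_trigger = y$schedule$final_death_trigger
    )
  } else analysis_schedule()
  ov <- if (!is.null(y$hr_overrides)) {
    do.call(rbind, lapply(y$hr_overrides, as.data.frame))
  } else NULL
  ns <- unlist(y$n_sites)
  scenario_config(
    entry_offsets = unlist(y$entry_offsets),
    n_sites = ns,
    accrual_per_site_year = y$accrual_per_site_year,
    cap = y$cap,
    control_median_ffs = y$control_median_ffs,
    control_median_os = y$control_median_os,
    schedule = sched,
    add_arm_lead_months = y$add_arm_lead_months,
    hr_overrides = ov,
    n_iterations = y$n_iterations
  )
}

#' @rdname read_scenario_config
#' @param config A [scenario_config()].
#' @export
write_scenario_config <- function(config, path) {
  stopifnot(inherits(config, "scenario_config"))
  y <- list(
    entry_offsets = config$entry_offsets,
    n_sites = as.list(config$n_sites),
    accrual_per_site_year = config$accrual_per_site_year,
    cap = config$cap,
    control_median_ffs = config$control_median_ffs,
    control_median_os = config$control_median_os,
    schedule = list(
      futility_event_triggers = config$schedule$futility_event_triggers,
      futility_hr_thresholds = config$schedule$futility_hr_thresholds,
      final_death_trigger = config$schedule$final_death_trigger
    ),
    add_arm_lead_months = config$add_arm_lead_months,
    n_iterations = config$n_iterations
  )
  if (!is.null(config$hr_overrides)) {
    ov <- config$hr_overrides
    y$hr_overrides <- lapply(seq_len(nrow(ov)), function(i) as.list(ov[i, ]))
  }
  yaml::write_yaml(y, path)
  invisible(path)
}
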