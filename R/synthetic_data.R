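# Synthetic inputs: expert-survey response tables with known ground truth
# (for exercising the moment-estimation path) and reduced-scale fixtures
# of the full scenario configuration for tests and examples.

#' Survey ground truth from a parameter table
#'
#' Treats each elicited parameter as the true distribution behind a
#' synthetic expert survey: responses are drawn from the same family
#' (lognormal costs, positive-normal times) with the tabulated mean/SD.
#'
#' @param table Parameter table ([default_parameter_table()]).
#' @param n_respondents Respondents per question (the real survey had 16
#'   completions; per-question counts varied and are not printed).
#' @return The table with an `n_respondents` column, class `survey_truth`.
#' @export
survey_truth <- function(table = default_parameter_table(),
                         n_respondents = 16L) {
  if (n_respondents < 2L)
    stop("at least two respondents are needed to estimate moments",
         call. = FALSE)
  validate_parameter_table(table)
  out <- table
  out$n_respondents <- as.integer(n_respondents)
  class(out) <- c("survey_truth", class(out))
  out
}

#' Generate synthetic expert-survey responses
#'
#' Per-parameter respondent draws from the truth distribution: lognormal
#' for costs (moment-matched, so the arithmetic mean/SD equal the truth)
#' and plain normal for times. Time responses are deliberately *not*
#' truncated at zero — truncation would bias the sample mean above the
#' elicited truth, and it is the analysis-side sampler
#' ([sample_parameter()]), not the survey emulator, that must produce
#' positive durations. [estimate_moments()] applied per parameter
#' therefore recovers the truth within ordinary sampling error; with
#' `sd = 0` all responses equal the mean.
#'
#' @param truth A [survey_truth()] table.
#' @return A tibble with columns `name`, `design_type`, `respondent`,
#'   `value` (one row per respondent per parameter).
#' @export
generate_survey_responses <- function(truth) {
  stopifnot(inherits(truth, "survey_truth"))
  rows <- lapply(seq_len(nrow(truth)), function(i) {
    p <- truth[i, ]
    v <- if (p$family == "normal") {
      stats::rnorm(p$n_respondents, p$mean, p$sd)
    } else {
      sample_parameter(p, p$n_respondents, anchor = "mean")
    }
    tibble::tibble(name = p$name, design_type = p$design_type,
                   respondent = seq_len(p$n_respondents), value = v)
  })
  do.call(rbind, rows)
}

#' Fit survey responses back to a parameter table
#'
#' Applies [estimate_moments()] per parameter, returning a table with the
#' same schema as [default_parameter_table()] (family/unit/basis copied
#' from the truth).
#'
#' @param responses Output of [generate_survey_responses()].
#' @param truth The matching [survey_truth()] (provides family/unit/basis).
#' @return A parameter table of estimated means/SDs.
#' @export
fit_survey_responses <- function(responses, truth) {
  out <- truth[, c("name", "design_type", "mean", "sd", "family", "unit",
                   "basis")]
  for (i in seq_len(nrow(out))) {
    v <- responses$value[responses$name == out$name[i] &
                           responses$design_type == out$design_type[i]]
    m <- estimate_moments(v)
    out$mean[i] <- m$mean
    out$sd[i] <- m$sd
  }
  class(out) <- class(tibble::tibble())
  out
}

#' Reduced-scale and full-scale study fixtures
#'
#' `"paper"` reproduces the full default configuration (futility triggers
#' 114/215/334 concurrent-control FFS events, final trigger 400 deaths,
#' caps 443, 5000 iterations). `"small"` shrinks the event triggers, caps
#' and iteration count roughly tenfold. `"tiny"` is a toy configuration
#' (triggers 3/5/7, final 8, caps 20, few sites) whose trials simulate in
#' well under a second; it also carries `unit_design`, a single fast
#' two-group design for unit tests.
#'
#' @param scale `"tiny"`, `"small"` or `"paper"`.
#' @return A list with `scale`, `config` (a [scenario_config()]),
#'   `parameter_table`, `scenarios` (the three base-case
#'   [build_scenario()] specs) and `unit_design`.
#' @export
make_fixture <- function(scale = c("tiny", "small", "paper")) {
  scale <- match.arg(scale)
  config <- switch(
    scale,
    paper = scenario_config(),
    small = scenario_config(
      schedule = analysis_schedule(c(11L, 22L, 33L), c(1.0, 0.92, 0.89), 40L),
      cap = 44L,
      n_iterations = 500L
    ),
    tiny = scenario_config(
      entry_offsets = c(0, 0, 0, 0, 0, 1, 1.5, 2, 2.5, 3),
      n_sites = c(platform = 12L, multigroup = 8L, two_group = 5L),
      accrual_per_site_year = 500 / 12,
      schedule = analysis_schedule(c(3L, 5L, 7L), c(1.0, 0.92, 0.89), 8L),
      cap = 20L,
      n_iterations = 20L
    )
  )
  unit_design <- trial_design(
    design_type = "two_group",
    arms = list(arm_spec("arm_1", hr_ffs = 0.75, hr_os = 0.75, cap = 20L)),
    n_sites = 5L,
    accrual_per_site_year = 20,
    schedule = analysis_schedule(c(3L, 5L, 7L), c(1.0, 0.92, 0.89), 8L)
  )
  list(scale = scale,
       config = config,
       parameter_table = default_parameter_table(),
       scenarios = lapply(1:3, build_scenario, effect_case = "base",
                          config = config),
       unit_design = unit_design)
}

#' Write a fixture's inputs to disk
#'
#' Serializes the parameter table (CSV) and scenario configuration (YAML)
#' in the same schemas the package consumes. Deterministic: repeated calls
#' produce byte-identical files.
#'
#' @param fixture A [make_fixture()] result.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_fixture <- function(fixture, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_parameter_table(fixture$parameter_table,
                        file.path(dir, "elicited_parameters.csv"))
  write_scenario_config(fixture$config, file.path(dir, "scenario_config.yaml"))
  invisible(dir)
}
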