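# Monte-Carlo driver and the matched-iteration comparison statistic.
# Scenarios are compared within each iteration (paired percent
# differences) and summarized by median and IQR.

#' Derive a reproducible sub-seed
#'
#' Hierarchical seeding: a master seed plus any mix of integer or character
#' components (iteration, scenario id, trial index, stream name) is hashed
#' to a 31-bit seed, so each (iteration, scenario, trial) gets its own
#' reproducible stream and adding a scenario never perturbs another's
#' draws.
#'
#' @param master Master seed (integer).
#' @param ... Further components (numbers or strings).
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(master, ...) {
  parts <- c(list(master), list(...))
  h <- 0
  for (p in parts) {
    if (is.character(p)) p <- sum(utf8ToInt(p)) else p <- as.numeric(p)
    h <- (h * 69069 + p + 1) %% 2147483647
  }
  as.integer(h)
}

#' Run matched Monte-Carlo simulations of competing scenarios
#'
#' For each iteration, the shared unit-cost parameters are drawn once (from
#' an iteration-specific stream) and applied to every scenario — common
#' random numbers — while each (iteration, scenario, trial) triple gets its
#' own stream for the trial simulation and design-specific setup draws.
#' Iterations are thereby matched across scenarios, which is what the
#' paired comparison statistic requires.
#'
#' @param scenarios List of `scenario_spec` objects ([build_scenario()]).
#' @param n_iter Number of Monte-Carlo iterations.
#' @param master_seed Master seed; all randomness derives from it.
#' @param param_table Elicited parameter table.
#' @param anchor Lognormal anchoring (`"mean"` or `"median"`).
#' @param setup_schedule Setup scheduling assumption (see [setup_time()]).
#' @param setup_only If `TRUE`, only setup costs and times are simulated
#'   (no trial engine, no conduct/analysis costs); duration and sample-size
#'   columns are `NA`. Orders of magnitude faster, and sufficient for
#'   setup-requirement comparisons.
#' @param progress Print a progress line every 100 iterations.
#' @return A tibble with one row per (iteration, scenario): cost components,
#'   `total_cost`, `setup_time`, `cumulative_duration` (sum over trials of
#'   setup time plus conduct span), `sample_size` and `n_forced` (arms whose
#'   final analysis had to be forced). Attributes `n_iterations` and
#'   `master_seed` record the run.
#' @export
run_monte_carlo <- function(scenarios, n_iter = 1000L, master_seed = 1L,
                            param_table = default_parameter_table(),
                            anchor = c("median", "mean"),
                            setup_schedule = c("protocol_then_parallel",
                                               "sequential"),
                            setup_only = FALSE, progress = FALSE) {
  anchor <- match.arg(anchor)
  setup_schedule <- match.arg(setup_schedule)
  if (n_iter < 1L) stop("`n_iter` must be at least 1", call. = FALSE)
  if (!is.list(scenarios) || length(scenarios) == 0L)
    stop("`scenarios` must be a non-empty list of scenario specs",
         call. = FALSE)
  if (inherits(scenarios, "scenario_spec")) scenarios <- list(scenarios)
  ids <- vapply(scenarios, `[[`, numeric(1), "id")

  nS <- length(scenarios)
  cols <- c("setup_cost", "conduct_cost", "analysis_cost", "add_arm_cost",
            "total_cost", "setup_time", "cumulative_duration",
            "sample_size", "n_forced")
  out <- matrix(NA_real_, nrow = n_iter * nS, ncol = length(cols),
                dimnames = list(NULL, cols))

  for (it in seq_len(n_iter)) {
    set.seed(derive_seed(master_seed, it, "shared"))
    shared <- draw_shared_parameters(param_table, anchor)
    for (si in seq_len(nS)) {
      sp <- scenarios[[si]]
      acc <- c(setup_cost = 0, conduct_cost = 0, analysis_cost = 0,
               add_arm_cost = 0, total_cost = 0, setup_time = 0,
               cumulative_duration = 0, sample_size = 0, n_forced = 0)
      for (ti in seq_along(sp$trials)) {
        design <- sp$trials[[ti]]
        set.seed(derive_seed(master_seed, it, sp$id, ti))
        setup <- draw_setup_parameters(param_table, design$design_type,
                                       anchor,
                                       site_setup = shared$site_setup)
        sc <- setup_cost(design, setup)
        st <- setup_time(setup, setup_schedule)
        acc["setup_cost"] <- acc["setup_cost"] + sc
        acc["setup_time"] <- acc["setup_time"] + st
        if (!setup_only) {
          entries <- vapply(design$arms, `[[`, numeric(1), "entry_time")
          n_added <- sum(entries > 0)
          delays <- NULL
          aac <- 0
          if (design$design_type == "platform" && n_added > 0L) {
            ad <- add_arm_cost_and_delay(n_added, param_table,
                                         design$design_type, anchor)
            aac <- ad$cost
            delays <- numeric(length(entries))
            delays[entries > 0] <- ad$delays_months
          }
          outc <- withCallingHandlers(
            simulate_trial(design, arm_delays = delays),
            warning = function(w) invokeRestart("muffleWarning")
          )
          cc <- conduct_cost(outc, shared)
          ac <- analysis_cost(outc, shared)
          acc["conduct_cost"] <- acc["conduct_cost"] + cc
          acc["analysis_cost"] <- acc["analysis_cost"] + ac
          acc["add_arm_cost"] <- acc["add_arm_cost"] + aac
          acc["cumulative_duration"] <- acc["cumulative_duration"] +
            st + outc$duration
          acc["sample_size"] <- acc["sample_size"] + outc$total_enrolled
          acc["n_forced"] <- acc["n_forced"] + outc$n_forced
        }
      }
      acc["total_cost"] <- acc["setup_cost"] + acc["conduct_cost"] +
        acc["analysis_cost"] + acc["add_arm_cost"]
      if (setup_only) {
        acc["cumulative_duration"] <- NA_real_
        acc["sample_size"] <- NA_real_
        acc["conduct_cost"] <- NA_real_
        acc["analysis_cost"] <- NA_real_
        acc["add_arm_cost"] <- NA_real_
        acc["total_cost"] <- NA_real_
        acc["n_forced"] <- NA_real_
      }
      out[(it - 1L) * nS + si, ] <- acc
    }
    if (progress && it %% 100L == 0L)
      message("iteration ", it, "/", n_iter)
  }

  res <- tibble::as_tibble(as.data.frame(out))
  res <- tibble::add_column(res,
                            iteration = rep(seq_len(n_iter), each = nS),
                            scenario = rep(ids, times = n_iter),
                            .before = 1L)
  attr(res, "n_iterations") <- n_iter
  attr(res, "master_seed") <- master_seed
  res
}

#' Matched-iteration relative differences
#'
#' The paired percent difference `100 * (comparator - reference) /
#' reference` computed within each Monte-Carlo iteration.
#'
#' @param reference,comparator Per-iteration values, matched by position.
#' @return Numeric vector of percentages.
#' @export
matched_relative_difference <- function(reference, comparator) {
  if (length(reference) != length(comparator))
    stop("reference and comparator must pair the same iterations",
         call. = FALSE)
  if (any(!is.finite(reference)) || any(!is.finite(comparator)))
    stop("relative differences require finite matched values", call. = FALSE)
  if (any(reference == 0))
    stop("relative difference undefined for zero reference values",
         call. = FALSE)
  100 * (comparator - reference) / reference
}

#' Summarize a distribution of matched differences
#'
#' Median, IQR (quartiles by linear interpolation, the default quantile
#' convention), mean and SD.
#'
#' @param values Numeric vector (at least one value).
#' @param quartile_type Quantile algorithm type passed to
#'   [stats::quantile()] (default 7, linear interpolation).
#' @return A one-row tibble with `median`, `q1`, `q3`, `mean`, `sd`, `n`.
#' @export
summarize_comparison <- function(values, quartile_type = 7) {
  if (length(values) == 0L || all(is.na(values)))
    stop("no values to summarize", call. = FALSE)
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), type = quartile_type,
                       names = FALSE)
  tibble::tibble(median = q[2], q1 = q[1], q3 = q[3],
                 mean = mean(values), sd = stats::sd(values),
                 n = length(values))
}

#' Compare scenarios against a reference by matched relative differences
#'
#' @param mc Result of [run_monte_carlo()].
#' @param metric Column to compare (e.g. `"total_cost"`,
#'   `"cumulative_duration"`, `"setup_time"`, `"setup_cost"`).
#' @param reference Reference scenario id (default 1, the platform).
#' @param comparators Scenario ids to compare (default: all others).
#' @return A tibble with one row per comparator: median/IQR/mean/SD of the
#'   per-iteration percent differences.
#' @export
compare_scenarios <- function(mc, metric = "total_cost", reference = 1,
                              comparators = NULL) {
  if (!metric %in% names(mc)) stop("unknown metric: ", metric, call. = FALSE)
  if (is.null(comparators))
    comparators <- setdiff(unique(mc$scenario), reference)
  ref <- mc[mc$scenario == reference, ]
  ref <- ref[order(ref$iteration), ]
  if (nrow(ref) == 0L)
    stop("reference scenario ", reference, " not present", call. = FALSE)
  rows <- lapply(comparators, function(s) {
    cmp <- mc[mc$scenario == s, ]
    cmp <- cmp[order(cmp$iteration), ]
    if (!identical(cmp$iteration, ref$iteration))
      stop("scenarios ", reference, " and ", s,
           " do not share matched iterations", call. = FALSE)
    d <- matched_relative_difference(ref[[metric]], cmp[[metric]])
    s_ <- summarize_comparison(d)
    tibble::add_column(s_, metric = metric, reference = reference,
                       scenario = s, .before = 1L)
  })
  do.call(rbind, rows)
}

#' Per-scenario descriptive summary
#'
#' Mean and SD of each simulated metric by scenario (absolute values, the
#' companion to the relative-difference summaries).
#'
#' @param mc Result of [run_monte_carlo()].
#' @return A tibble with one row per (scenario, metric).
#' @export
scenario_summary <- function(mc) {
  metrics <- setdiff(names(mc), c("iteration", "scenario"))
  rows <- list()
  for (s in unique(mc$scenario)) {
    sub <- mc[mc$scenario == s, ]
    for (m in metrics) {
      v <- sub[[m]]
      if (all(is.na(v))) next
      rows[[length(rows) + 1L]] <- tibble::tibble(
        scenario = s, metric = m, mean = mean(v, na.rm = TRUE),
        sd = stats::sd(v, na.rm = TRUE),
        median = stats::median(v, na.rm = TRUE))
    }
  }
  do.call(rbind, rows)
}
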