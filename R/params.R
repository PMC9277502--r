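# Elicited cost/time parameters and their sampling distributions.
#
# Costs are modelled as lognormal, times as (positive) normal; both are
# parameterized from an elicited arithmetic mean and SD by the method of
# moments.

#' Lognormal parameters from an arithmetic mean and SD
#'
#' Inverts the moment equations of the lognormal distribution so that draws
#' have arithmetic mean `mean` and arithmetic standard deviation `sd`:
#' `sdlog^2 = log(1 + (sd/mean)^2)` and `meanlog = log(mean) - sdlog^2 / 2`.
#'
#' @param mean Positive arithmetic mean of the target distribution.
#' @param sd Non-negative arithmetic standard deviation. `sd = 0` gives the
#'   degenerate point mass at `mean` (`meanlog = log(mean)`, `sdlog = 0`).
#' @return A list with elements `meanlog` and `sdlog`, usable directly with
#'   [stats::rlnorm()].
#' @examples
#' lognormal_from_moments(9440, 14086)
#' @export
lognormal_from_moments <- function(mean, sd) {
  if (!is.numeric(mean) || length(mean) != 1L || !is.finite(mean) || mean <= 0)
    stop("`mean` must be a single positive number", call. = FALSE)
  if (!is.numeric(sd) || length(sd) != 1L || !is.finite(sd) || sd < 0)
    stop("`sd` must be a single non-negative number", call. = FALSE)
  s2 <- log(1 + (sd / mean)^2)
  list(meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
}

#' Sample an elicited parameter
#'
#' Draws from the distribution implied by one elicited parameter: lognormal
#' for costs (moment-matched via [lognormal_from_moments()], or anchored at
#' the median with `anchor = "median"`, i.e. `meanlog = log(mean)`), normal
#' for times. Normal draws are constrained positive by rejection resampling,
#' which preserves the distribution's shape above zero instead of creating a
#' point mass at zero.
#'
#' @param param A list or one-row data frame with fields `mean`, `sd` and
#'   `family` (`"lognormal"` or `"normal"`).
#' @param n Number of draws.
#' @param anchor For lognormal parameters, whether the elicited mean is the
#'   median (`"median"`, the default: simulated cost scales then exceed the
#'   elicited means, matching how the elicited values behave in the
#'   programme-level cost model) or the arithmetic mean (`"mean"`, the
#'   moment-preserving alternative) of the fitted distribution.
#' @return Numeric vector of `n` positive draws.
#' @export
sample_parameter <- function(param, n = 1L, anchor = c("median", "mean")) {
  anchor <- match.arg(anchor)
  mean <- as.numeric(param$mean)
  sd <- as.numeric(param$sd)
  family <- as.character(param$family)
  if (!is.finite(mean) || mean <= 0)
    stop("elicited mean must be positive", call. = FALSE)
  if (!is.finite(sd) || sd < 0)
    stop("elicited sd must be non-negative", call. = FALSE)
  if (n == 0L) return(numeric(0))
  if (sd == 0) return(rep(mean, n))
  if (family == "lognormal") {
    if (anchor == "mean") {
      p <- lognormal_from_moments(mean, sd)
    } else {
      p <- list(meanlog = log(mean), sdlog = sqrt(log(1 + (sd / mean)^2)))
    }
    stats::rlnorm(n, p$meanlog, p$sdlog)
  } else if (family == "normal") {
    x <- stats::rnorm(n, mean, sd)
    bad <- which(x <= 0)
    while (length(bad) > 0L) {
      x[bad] <- stats::rnorm(length(bad), mean, sd)
      bad <- bad[x[bad] <= 0]
    }
    x
  } else {
    stop("unknown distribution family: ", family, call. = FALSE)
  }
}

#' Sample mean and SD of survey responses
#'
#' @param responses Numeric vector of at least two elicited responses.
#' @return A list with `mean` (sample mean) and `sd` (sample SD, denominator
#'   `n - 1`).
#' @export
estimate_moments <- function(responses) {
  responses <- as.numeric(responses)
  if (length(responses) < 2L || anyNA(responses))
    stop("at least two non-missing responses are required", call. = FALSE)
  list(mean = mean(responses), sd = stats::sd(responses))
}

# design types a parameter row may apply to
.design_types <- c("two_group", "multigroup", "platform", "shared")

#' Elicited parameter table for trial cost and time requirements
#'
#' Returns the expert-elicited cost and time parameters used throughout the
#' costing model: per-design-type setup costs and times (protocol
#' development, trial approvals, database development), the shared per-site
#' setup cost, shared conduct rates (recruitment per patient, monthly
#' follow-up per patient, monthly site management per site, monthly database
#' management), shared per-group analysis costs (interim, final), and the
#' platform-only cost and lead time of adding a new intervention group.
#' Costs are in 2021 US dollars (undiscounted), times in months.
#'
#' The same table ships as a CSV at
#' `system.file("extdata", "elicited_parameters.csv", package = "platformcost")`.
#'
#' @return A tibble with columns `name`, `design_type`, `mean`, `sd`,
#'   `family`, `unit`, `basis`.
#' @export
default_parameter_table <- function() {
  rows <- function(name, means, sds, basis = "per_trial") {
    tibble::tibble(
      name = name,
      design_type = c("two_group", "multigroup", "platform"),
      mean = means, sd = sds,
      family = "lognormal", unit = "USD2021", basis = basis
    )
  }
  trow <- function(name, means, sds) {
    tibble::tibble(
      name = name,
      design_type = c("two_group", "multigroup", "platform"),
      mean = means, sd = sds,
      family = "normal", unit = "months", basis = "per_trial"
    )
  }
  shared <- function(name, mean, sd, basis, family = "lognormal",
                     unit = "USD2021", design_type = "shared") {
    tibble::tibble(name = name, design_type = design_type, mean = mean,
                   sd = sd, family = family, unit = unit, basis = basis)
  }
  tab <- rbind(
    rows("protocol_development", c(123333, 136667, 155667), c(23245, 22480, 34347)),
    rows("trial_approvals",      c(151183, 165367, 172250), c(28126, 27200, 38538)),
    rows("database_development", c(32500, 36667, 42500),    c(30406, 34763, 30625)),
    shared("site_setup", 9440, 14086, "per_site"),
    trow("protocol_development_time", c(3.92, 5.09, 8.78), c(1.98, 2.26, 3.83)),
    trow("trial_approvals_time",      c(3.67, 4.00, 6.50), c(2.06, 2.40, 4.14)),
    trow("database_development_time", c(2.80, 3.20, 5.40), c(1.30, 1.30, 1.95)),
    shared("recruitment_per_patient",     1300, 476,  "per_patient"),
    shared("monthly_followup_per_patient", 313, 132,  "per_patient_month"),
    shared("monthly_site_management",     5000, 3162, "per_site_month"),
    shared("monthly_database_management", 2500, 1061, "per_trial_month"),
    shared("interim_analysis_per_group", 12883, 29417, "per_group_analysis"),
    shared("final_analysis_per_group",   42750, 37053, "per_group_analysis"),
    shared("add_group_cost", 75626, 43528, "per_added_group",
           design_type = "platform"),
    shared("add_group_time", 3.00, 1.73, "per_added_group", family = "normal",
           unit = "months", design_type = "platform")
  )
  tibble::as_tibble(tab)
}

#' Look up one elicited parameter
#'
#' @param table A parameter table as returned by [default_parameter_table()].
#' @param name Parameter name.
#' @param design_type One of `"two_group"`, `"multigroup"`, `"platform"`,
#'   `"shared"`. Shared parameters are found regardless of the design type
#'   asked for.
#' @return A one-row tibble.
#' @export
param_lookup <- function(table, name, design_type = "shared") {
  hit <- table[table$name == name &
                 (table$design_type == design_type |
                    table$design_type == "shared"), , drop = FALSE]
  if (nrow(hit) == 0L)
    stop("no parameter `", name, "` for design type `", design_type, "`",
         call. = FALSE)
  hit[1L, ]
}

#' Validate a parameter table
#'
#' Checks the schema (columns, enumerations), positivity of means,
#' non-negativity of SDs, and the family/unit pairing (costs lognormal,
#' times normal).
#'
#' @param table A candidate parameter table.
#' @return The table, invisibly, if valid; otherwise an error listing every
#'   offending row.
#' @export
validate_parameter_table <- function(table) {
  needed <- c("name", "design_type", "mean", "sd", "family", "unit", "basis")
  missing_cols <- setdiff(needed, names(table))
  if (length(missing_cols) > 0L)
    stop("parameter table is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  problems <- character(0)
  bad <- function(cond, msg) {
    idx <- which(cond)
    if (length(idx) > 0L)
      problems <<- c(problems, paste0("row ", idx, " (", table$name[idx],
                                      "): ", msg))
  }
  bad(!(table$design_type %in% .design_types), "unknown design_type")
  bad(!is.finite(table$mean) | table$mean <= 0, "mean must be positive")
  bad(!is.finite(table$sd) | table$sd < 0, "sd must be non-negative")
  bad(!(table$family %in% c("lognormal", "normal")), "unknown family")
  bad(!(table$unit %in% c("USD2021", "months")), "unknown unit")
  bad(table$unit == "USD2021" & table$family != "lognormal",
      "costs must be lognormal")
  bad(table$unit == "months" & table$family != "normal",
      "times must be normal")
  if (length(problems) > 0L)
    stop("invalid parameter table:\n",
         paste0("  ", problems, collapse = "\n"), call. = FALSE)
  invisible(table)
}

#' Read / write a parameter table as CSV
#'
#' @param path File path.
#' @return `read_parameter_table()` returns a validated tibble;
#'   `write_parameter_table()` returns `path` invisibly.
#' @export
read_parameter_table <- function(path) {
  if (!file.exists(path))
    stop("parameter table not found: ", path, call. = FALSE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_parameter_table(tab)
  tibble::as_tibble(tab)
}

#' @rdname read_parameter_table
#' @param table A parameter table.
#' @export
write_parameter_table <- function(table, path) {
  validate_parameter_table(table)
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
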