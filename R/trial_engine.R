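# Event-driven simulation of multi-arm survival trials with a shared
# control group. Interim futility analyses on failure-free survival (FFS)
# and the final overall-survival (OS) analysis are triggered when the
# concurrent control group of each intervention arm reaches prespecified
# event counts. Internal calendar unit is years; elicited medians and lead
# times are months (12 months/year exactly).

#' Analysis schedule for an event-driven trial
#'
#' @param futility_event_triggers Strictly increasing concurrent-control FFS
#'   event counts at which the interim futility analyses are run.
#' @param futility_hr_thresholds Non-increasing FFS hazard-ratio thresholds;
#'   an arm whose estimated HR is at or above the stage threshold stops for
#'   futility (ties stop).
#' @param final_death_trigger Concurrent-control death count triggering the
#'   final OS analysis.
#' @return A list of class `analysis_schedule`.
#' @export
analysis_schedule <- function(futility_event_triggers = c(114L, 215L, 334L),
                              futility_hr_thresholds = c(1.0, 0.92, 0.89),
                              final_death_trigger = 400L) {
  trig <- as.integer(futility_event_triggers)
  thr <- as.numeric(futility_hr_thresholds)
  if (length(trig) != length(thr))
    stop("triggers and thresholds must have the same length", call. = FALSE)
  if (length(trig) > 0L) {
    if (any(diff(trig) <= 0L))
      stop("futility event triggers must be strictly increasing", call. = FALSE)
    if (isTRUE(any(diff(thr) > 0)))   # diff over infinite thresholds is NaN
      stop("futility HR thresholds must be non-increasing", call. = FALSE)
  }
  if (final_death_trigger < 1L)
    stop("final death trigger must be positive", call. = FALSE)
  structure(list(futility_event_triggers = trig,
                 futility_hr_thresholds = thr,
                 final_death_trigger = as.integer(final_death_trigger)),
            class = "analysis_schedule")
}

#' Intervention arm specification
#'
#' @param label Arm label.
#' @param entry_time Years from trial start at which the arm enters the
#'   trial (0 for initial arms; positive entries are platform additions).
#' @param hr_ffs,hr_os Hazard ratios versus control for failure-free and
#'   overall survival; must be positive.
#' @param cap Maximum number of patients randomized to the arm.
#' @param allocation_weight Randomization weight while the arm is open.
#' @return A list of class `arm_spec`.
#' @export
arm_spec <- function(label, entry_time = 0, hr_ffs = 0.75, hr_os = 0.75,
                     cap = 443L, allocation_weight = 1) {
  if (hr_ffs <= 0 || hr_os <= 0)
    stop("hazard ratios must be positive", call. = FALSE)
  if (cap < 1L) stop("arm cap must be positive", call. = FALSE)
  if (entry_time < 0) stop("entry_time must be non-negative", call. = FALSE)
  structure(list(label = as.character(label), entry_time = entry_time,
                 hr_ffs = hr_ffs, hr_os = hr_os, cap = as.integer(cap),
                 allocation_weight = allocation_weight),
            class = "arm_spec")
}

#' Trial design
#'
#' @param design_type `"two_group"`, `"multigroup"` or `"platform"`.
#' @param arms List of [arm_spec()] objects. At least one arm must have
#'   `entry_time = 0`; only platform designs may have later entries.
#' @param n_sites Number of recruiting sites; defaults to 120 (platform),
#'   80 (multigroup) or 50 (two-group).
#' @param accrual_per_site_year Patients recruited per site per year
#'   (default 500/120, i.e. a 120-site platform recruits 500 per year).
#' @param control_weight_initial Randomization weight of the control group
#'   while at least one initial arm is open and control enrollment is below
#'   twice the arm cap; defaults to 2 when there are two or more initial
#'   arms (the 2:1:1:1:1:1 allocation) and 1 otherwise.
#' @param control_median_ffs,control_median_os Control-arm median FFS and OS
#'   in months (exponential event-time model).
#' @param schedule An [analysis_schedule()].
#' @param add_arm_lead_months Default activation lag, in months, between a
#'   platform arm's entry time and the start of its recruitment.
#' @return A list of class `trial_design`.
#' @export
trial_design <- function(design_type = c("two_group", "multigroup", "platform"),
                         arms,
                         n_sites = NULL,
                         accrual_per_site_year = 500 / 120,
                         control_weight_initial = NULL,
                         control_median_ffs = 12,
                         control_median_os = 24,
                         schedule = analysis_schedule(),
                         add_arm_lead_months = 3) {
  design_type <- match.arg(design_type)
  if (missing(arms) || length(arms) == 0L)
    stop("a trial design needs at least one intervention arm", call. = FALSE)
  if (is.null(n_sites))
    n_sites <- switch(design_type, platform = 120L, multigroup = 80L,
                      two_group = 50L)
  entries <- vapply(arms, function(a) a$entry_time, numeric(1))
  if (!any(entries == 0))
    stop("at least one arm must enter at time 0", call. = FALSE)
  if (design_type != "platform" && any(entries > 0))
    stop("only platform designs can add arms after initiation", call. = FALSE)
  if (control_median_ffs <= 0 || control_median_os <= 0)
    stop("control medians must be positive", call. = FALSE)
  if (control_median_ffs > control_median_os)
    stop("control median FFS cannot exceed median OS", call. = FALSE)
  if (is.null(control_weight_initial))
    control_weight_initial <- if (sum(entries == 0) >= 2L) 2 else 1
  structure(list(design_type = design_type, arms = arms,
                 n_sites = as.integer(n_sites),
                 accrual_per_site_year = accrual_per_site_year,
                 control_weight_initial = control_weight_initial,
                 control_median_ffs = control_median_ffs,
                 control_median_os = control_median_os,
                 schedule = schedule,
                 add_arm_lead_months = add_arm_lead_months),
            class = "trial_design")
}

#' Exponential event times under a hazard ratio
#'
#' Draws event times (months) from an exponential distribution with hazard
#' `log(2) / control_median * hr`, so the median of the distribution is
#' `control_median / hr`.
#'
#' @param n Number of draws.
#' @param control_median Control-group median event time in months.
#' @param hr Hazard ratio versus control.
#' @return Numeric vector of `n` event times in months.
#' @export
draw_event_times <- function(n, control_median, hr = 1) {
  if (control_median <= 0) stop("median must be positive", call. = FALSE)
  if (hr <= 0) stop("hazard ratio must be positive", call. = FALSE)
  if (n == 0L) return(numeric(0))
  stats::rexp(n, rate = log(2) / control_median * hr)
}

#' Count events among an arm's concurrent controls
#'
#' Concurrent controls of an arm are control patients enrolled while the
#' arm was under evaluation: enrollment in `[window_start, min(window_end,
#' t)]`. Only their events observed by calendar time `t` count toward the
#' arm's analysis triggers.
#'
#' @param control_enroll Calendar enrollment times of control patients.
#' @param control_event Calendar event times (FFS failure or death).
#' @param window_start Arm activation time.
#' @param t Calendar time of the count.
#' @param window_end Arm stop time, if the arm has stopped (default `Inf`).
#' @return Integer event count.
#' @export
concurrent_control_count <- function(control_enroll, control_event,
                                     window_start, t, window_end = Inf) {
  if (t < window_start)
    stop("count time precedes the arm's activation", call. = FALSE)
  inw <- control_enroll >= window_start &
    control_enroll <= min(window_end, t)
  sum(inw & control_event <= t)
}

#' Interim futility decision
#'
#' @param hr_estimate Estimated FFS hazard ratio at the interim.
#' @param stage Interim stage (1-based).
#' @param schedule An [analysis_schedule()].
#' @return `"stop_futility"` if the estimate is at or above the stage
#'   threshold (ties stop), else `"continue"`.
#' @export
interim_decision <- function(hr_estimate, stage, schedule = analysis_schedule()) {
  thr <- schedule$futility_hr_thresholds
  if (stage < 1L || stage > length(thr))
    stop("invalid interim stage", call. = FALSE)
  if (hr_estimate >= thr[stage]) "stop_futility" else "continue"
}

#' Simulate one event-driven trial
#'
#' Advances calendar time through patient accrual (deterministic equal
#' spacing at the aggregate rate `n_sites * accrual_per_site_year`),
#' randomization among the open groups proportional to allocation weights,
#' event-count-triggered interim futility analyses (log-rank on FFS against
#' the arm's concurrent controls) and the final OS analysis when the arm's
#' concurrent-control deaths reach the final trigger. Arms stopped for
#' futility stop randomizing immediately; enrollment pauses whenever no arm
#' is open. Patient event times are independent exponentials with the
#' arm-specific hazard ratios; the latent FFS time is the minimum of the
#' FFS and OS draws, so failure-free survival always precedes death.
#'
#' If an arm's trigger can never be reached (enrollment has permanently
#' ended and too few concurrent controls exist), a final analysis is forced
#' at the last possible event time and flagged in the outcome.
#'
#' @param design A [trial_design()].
#' @param arm_delays Optional numeric vector (months), one per arm, of
#'   activation lags added to positive entry times (e.g. sampled
#'   add-a-group lead times). Defaults to `add_arm_lead_months` for every
#'   added arm.
#' @param keep_patients If `TRUE`, the outcome carries a `patients` data
#'   frame (enrollment time, group, latent FFS/OS calendar times) for
#'   diagnostics; off by default to keep Monte-Carlo runs light.
#' @return A list of class `trial_outcome` with the trial end time and
#'   duration (years of conduct), enrollment totals, follow-up exposure
#'   (`patient_months`, `site_months`, `trial_months`), a per-arm
#'   data frame `arms` (stop reason, stop time, analyses performed) and an
#'   `analyses` data frame logging every interim/final analysis (arm,
#'   stage, calendar time, estimated HR, decision).
#' @export
simulate_trial <- function(design, arm_delays = NULL, keep_patients = FALSE) {
  stopifnot(inherits(design, "trial_design"))
  arms <- design$arms
  A <- length(arms)
  entry <- vapply(arms, `[[`, numeric(1), "entry_time")
  if (is.null(arm_delays)) {
    arm_delays <- ifelse(entry > 0, design$add_arm_lead_months, 0)
  }
  if (length(arm_delays) != A)
    stop("`arm_delays` must have one entry per arm", call. = FALSE)
  if (any(arm_delays < 0))
    stop("activation delays must be non-negative", call. = FALSE)
  act <- entry + ifelse(entry > 0, arm_delays / 12, 0)
  hrf <- vapply(arms, `[[`, numeric(1), "hr_ffs")
  hro <- vapply(arms, `[[`, numeric(1), "hr_os")
  cap <- vapply(arms, `[[`, integer(1), "cap")
  wt <- vapply(arms, `[[`, numeric(1), "allocation_weight")
  labels <- vapply(arms, `[[`, character(1), "label")
  initial <- entry == 0

  sch <- design$schedule
  trig <- sch$futility_event_triggers
  thr <- sch$futility_hr_thresholds
  n_stages <- length(trig)
  ftrig <- sch$final_death_trigger

  lam_f <- log(2) * 12 / design$control_median_ffs   # per year
  lam_o <- log(2) * 12 / design$control_median_os
  rate <- design$n_sites * design$accrual_per_site_year
  gap <- 1 / rate
  cw0 <- design$control_weight_initial
  ctl_cap2 <- 2L * max(cap[initial])

  # patient stores (controls and intervention patients kept separately,
  # both appended in enrollment order)
  nb <- sum(cap) + ctl_cap2 + 64L
  cu <- numeric(nb); cf <- numeric(nb); co <- numeric(nb); nc <- 0L
  au <- numeric(nb); af <- numeric(nb); ao <- numeric(nb)
  ag <- integer(nb); na_ <- 0L
  grow <- function(x, need) {
    while (length(x) < need) x <- c(x, numeric(length(x)))
    x
  }

  alive <- rep(TRUE, A)
  stage <- rep(1L, A)
  if (n_stages == 0L) stage <- rep(0L, A)  # straight to final
  n_enr <- integer(A)
  stop_time <- rep(NA_real_, A)
  stop_reason <- rep(NA_character_, A)
  n_interims <- integer(A)
  final_perf <- rep(FALSE, A)
  forced <- rep(FALSE, A)
  hr_final <- rep(NA_real_, A)
  an_log <- list()   # one row per analysis: arm, stage (0 = final), t, hr

  frontier <- 0
  next_arrival <- gap

  draw_patients <- function(u, hr_ffs, hr_os) {
    m <- length(u)
    os <- u + stats::rexp(m, lam_o * hr_os)
    ffs <- pmin(u + stats::rexp(m, lam_f * hr_ffs), os)
    list(ffs = ffs, os = os)
  }

  # unequal allocation (control weight 2) holds while at least one initial
  # arm is still open and control enrollment is below twice the arm cap
  control_weight <- function() {
    if (cw0 > 1 && nc < ctl_cap2 &&
        any(initial & alive & act <= frontier & n_enr < cap))
      cw0 else 1
  }

  # candidate analysis time for arm a at its current stage: the k-th
  # smallest event time among controls enrolled at or after activation.
  # Cached; a cache entry goes stale when controls are added or removed or
  # the arm's stage advances.
  cand <- rep(Inf, A)
  cand_stale <- rep(TRUE, A)
  candidate <- function(a) {
    s <- stage[a]
    k <- if (s >= 1L && s <= n_stages) trig[s] else ftrig
    i0 <- findInterval(act[a], cu[seq_len(nc)]) + 1L
    m <- nc - i0 + 1L
    if (m < k) return(Inf)
    ev <- if (s >= 1L && s <= n_stages) cf[i0:nc] else co[i0:nc]
    sort(ev, partial = k)[k]
  }

  run_analysis <- function(a, T, final_stage, is_forced) {
    s <- stage[a]
    i0 <- findInterval(act[a], cu[seq_len(nc)]) + 1L
    j1 <- findInterval(T, cu[seq_len(nc)])
    cidx <- if (j1 >= i0) i0:j1 else integer(0)
    aidx <- which(ag[seq_len(na_)] == a & au[seq_len(na_)] <= T)
    if (final_stage) {
      e <- c(co[cidx], ao[aidx])
    } else {
      e <- c(cf[cidx], af[aidx])
    }
    u <- c(cu[cidx], au[aidx])
    grp <- c(rep(0L, length(cidx)), rep(1L, length(aidx)))
    obs <- pmin(e, T) - u
    ev <- as.integer(e <= T)
    hr_est <- if (sum(ev) > 0L && length(unique(grp)) == 2L) {
      r <- .logrank_core(obs, ev, grp)
      if (r$v > 0) exp((r$o1 - r$e1) / r$v) else NA_real_
    } else NA_real_

    if (!final_stage) {
      stop_it <- !is.na(hr_est) && hr_est >= thr[s]
      if (stop_it) {
        alive[a] <<- FALSE
        stop_time[a] <<- T
        stop_reason[a] <<- paste0("futility_stage_", s)
        n_interims[a] <<- s
      } else {
        n_interims[a] <<- s
        stage[a] <<- s + 1L
        if (stage[a] > n_stages) stage[a] <<- 0L  # 0 marks "final next"
      }
      stopped <- stop_it
    } else {
      alive[a] <<- FALSE
      stop_time[a] <<- T
      stop_reason[a] <<- "final_analysis"
      final_perf[a] <<- TRUE
      forced[a] <<- is_forced
      hr_final[a] <<- hr_est
      stopped <- TRUE
    }
    an_log[[length(an_log) + 1L]] <<-
      c(arm = a, stage = if (final_stage) 0L else s, time = T,
        hr = if (is.na(hr_est)) NA_real_ else hr_est,
        stopped = as.integer(stopped))
    cand_stale[a] <<- TRUE
    if (stopped) truncate_after(a, T)
    invisible(NULL)
  }

  # When an arm that was still randomizing stops at T, arrivals generated
  # beyond T were allocated under a regime that no longer holds; drop them
  # (arrival times are deterministic, so they are regenerated with the
  # correct allocation on the next extension).
  truncate_after <- function(a, T) {
    # "open" is judged at the analysis time T: patients generated beyond T
    # may have pushed the arm to its cap, but allocation in (T, frontier]
    # still assumed the arm was available
    aidx <- which(ag[seq_len(na_)] == a)
    n_at_T <- sum(au[aidx] <= T)
    was_open <- n_at_T < cap[a] && act[a] <= frontier
    if (!was_open) return(invisible(NULL))
    dropped <- Inf
    ncn <- findInterval(T, cu[seq_len(nc)])
    if (ncn < nc) dropped <- min(dropped, cu[ncn + 1L])
    nan <- findInterval(T, au[seq_len(na_)])
    if (nan < na_) dropped <- min(dropped, au[nan + 1L])
    if (is.finite(dropped)) {
      if (ncn < nc) cand_stale[] <<- TRUE
      nc <<- ncn
      na_ <<- nan
      n_enr <<- tabulate(ag[seq_len(na_)], A)
      next_arrival <<- dropped
    }
    frontier <<- min(frontier, T)
    invisible(NULL)
  }

  extend_enrollment <- function(target) {
    open <- which(alive & act <= frontier & n_enr < cap)
    if (length(open) == 0L || next_arrival > target) {
      frontier <<- target
      return(invisible(NULL))
    }
    m <- floor((target - next_arrival) / gap) + 1L
    arr <- next_arrival + gap * (0:(m - 1L))
    cw <- control_weight()
    groups <- c(0L, open)
    g <- groups[sample.int(length(groups), m, replace = TRUE,
                           prob = c(cw, wt[open]))]
    # truncate the chunk at the first cap hit (arm caps; control weight
    # threshold during the unequal-allocation phase)
    p_hit <- Inf
    chunk_counts <- tabulate(g + 1L, A + 1L)
    if (cw > 1 && chunk_counts[1L] >= ctl_cap2 - nc)
      p_hit <- min(p_hit, which(g == 0L)[ctl_cap2 - nc])
    for (j in open) {
      room <- cap[j] - n_enr[j]
      if (chunk_counts[j + 1L] >= room)
        p_hit <- min(p_hit, which(g == j)[room])
    }
    truncated <- is.finite(p_hit)
    p <- if (truncated) as.integer(p_hit) else m
    keep <- seq_len(p)
    g <- g[keep]; arr <- arr[keep]
    is_c <- g == 0L
    mc <- sum(is_c)
    if (mc > 0L) {
      cu <<- grow(cu, nc + mc); cf <<- grow(cf, nc + mc); co <<- grow(co, nc + mc)
      d <- draw_patients(arr[is_c], 1, 1)
      cu[nc + seq_len(mc)] <<- arr[is_c]
      cf[nc + seq_len(mc)] <<- d$ffs
      co[nc + seq_len(mc)] <<- d$os
      nc <<- nc + mc
      cand_stale[] <<- TRUE
    }
    ma <- p - mc
    if (ma > 0L) {
      ga <- g[!is_c]
      d <- draw_patients(arr[!is_c], hrf[ga], hro[ga])
      au <<- grow(au, na_ + ma); af <<- grow(af, na_ + ma)
      ao <<- grow(ao, na_ + ma); ag <<- grow(ag, na_ + ma)
      au[na_ + seq_len(ma)] <<- arr[!is_c]
      af[na_ + seq_len(ma)] <<- d$ffs
      ao[na_ + seq_len(ma)] <<- d$os
      ag[na_ + seq_len(ma)] <<- ga
      na_ <<- na_ + ma
      n_enr <<- n_enr + tabulate(ga, A)
    }
    next_arrival <<- arr[p] + gap
    frontier <<- if (truncated) arr[p] else target
    invisible(NULL)
  }

  n_forced <- 0L
  iter_guard <- 0L
  repeat {
    iter_guard <- iter_guard + 1L
    if (iter_guard > 200000L)
      stop("trial simulation failed to terminate", call. = FALSE)
    live <- which(alive)
    if (length(live) == 0L) break

    activated <- alive & act <= frontier
    waiting <- alive & act > frontier
    next_act <- if (any(waiting)) min(act[waiting]) else Inf

    for (a in which(activated & cand_stale)) {
      cand[a] <- candidate(a)
      cand_stale[a] <- FALSE
    }
    consider <- cand
    consider[!activated] <- Inf
    amin <- which.min(consider)
    cmin <- consider[amin]

    open_any <- any(alive & act <= frontier & n_enr < cap)

    if (cmin <= frontier) {
      run_analysis(amin, cmin, final_stage = stage[amin] == 0L,
                   is_forced = FALSE)
    } else if (open_any) {
      target <- min(cmin, next_act)
      if (!is.finite(target)) target <- frontier + 2
      extend_enrollment(target)
    } else if (is.finite(next_act) && next_act <= cmin) {
      frontier <- next_act
      next_arrival <- next_act + gap
    } else if (is.finite(cmin)) {
      # no enrollment can occur before the analysis time
      frontier <- max(frontier, cmin)
      run_analysis(amin, cmin, final_stage = stage[amin] == 0L,
                   is_forced = FALSE)
    } else {
      # enrollment has permanently ended and no trigger is reachable:
      # force the final analysis at the last possible event time
      tf <- rep(Inf, A)
      for (a in live) {
        i0 <- findInterval(act[a], cu[seq_len(nc)]) + 1L
        ev <- c(if (i0 <= nc) co[i0:nc] else numeric(0),
                ao[seq_len(na_)][ag[seq_len(na_)] == a])
        tf[a] <- if (length(ev) > 0L) max(ev) else frontier
      }
      af_min <- which.min(tf)
      stage[af_min] <- 0L
      frontier <- max(frontier, tf[af_min])
      run_analysis(af_min, tf[af_min], final_stage = TRUE, is_forced = TRUE)
      n_forced <- n_forced + 1L
    }
  }

  if (n_forced > 0L)
    warning(sprintf(paste0("%d arm(s) could not reach their event trigger; ",
                           "final analysis forced at the last possible ",
                           "event time"), n_forced), call. = FALSE)

  end_time <- max(stop_time)
  ctl_fu <- if (nc > 0L) sum(pmin(co[seq_len(nc)], end_time) - cu[seq_len(nc)]) else 0
  arm_fu <- if (na_ > 0L) {
    idx <- seq_len(na_)
    sum(pmin(ao[idx], stop_time[ag[idx]]) - au[idx])
  } else 0

  an_df <- as.data.frame(do.call(rbind, an_log))
  an_df$label <- labels[an_df$arm]
  patients <- if (keep_patients) {
    idx <- seq_len(na_)
    data.frame(
      enroll_time = c(cu[seq_len(nc)], au[idx]),
      group = c(rep("control", nc), labels[ag[idx]]),
      ffs_cal = c(cf[seq_len(nc)], af[idx]),
      os_cal = c(co[seq_len(nc)], ao[idx]),
      stringsAsFactors = FALSE
    )
  } else NULL

  structure(list(
    design_type = design$design_type,
    n_sites = design$n_sites,
    start_time = 0,
    end_time = end_time,
    duration = end_time,
    total_enrolled = nc + na_,
    n_control = nc,
    patient_months = (ctl_fu + arm_fu) * 12,
    site_months = design$n_sites * end_time * 12,
    trial_months = end_time * 12,
    n_forced = n_forced,
    analyses = an_df,
    patients = patients,
    arms = data.frame(
      label = labels,
      entry_time = entry,
      activation_time = act,
      n_enrolled = n_enr,
      stop_reason = stop_reason,
      stop_time = stop_time,
      n_interims_performed = n_interims,
      final_performed = final_perf,
      forced = forced,
      hr_final = hr_final,
      stringsAsFactors = FALSE
    )
  ), class = "trial_outcome")
}

#' @export
print.trial_outcome <- function(x, ...) {
  cat(sprintf("<trial_outcome: %s, %d patients, %.2f years>\n",
              x$design_type, x$total_enrolled, x$duration))
  print(x$arms[, c("label", "n_enrolled", "stop_reason", "stop_time",
                   "n_interims_performed", "final_performed")])
  invisible(x)
}
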