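# Two-sample log-rank test with the hypergeometric variance, plus the
# one-step hazard-ratio estimate exp((O1 - E1) / V) used at interim and
# final analyses.

#' Two-sample log-rank test
#'
#' Standard (unweighted) log-rank test comparing an intervention group
#' against control, with the hypergeometric variance at each distinct event
#' time (tied event times are handled by the usual grouped computation).
#' Also returns the one-step estimate of the hazard ratio
#' `exp((O1 - E1) / V)`, where group 1 is the intervention: values above 1
#' indicate more events on the intervention than expected under equal
#' hazards.
#'
#' @param time Follow-up times (any unit), right-censored.
#' @param event Event indicator (1 = event, 0 = censored).
#' @param group Group indicator (1/TRUE = intervention, 0/FALSE = control).
#' @return A list with `chisq`, `hr` (the one-step HR estimate), `o1`, `e1`
#'   and `v` (observed events, expected events and variance for the
#'   intervention group).
#' @examples
#' logrank_test(c(1, 2, 3, 4), c(1, 1, 1, 1), c(1, 1, 0, 0))
#' @export
logrank_test <- function(time, event, group) {
  time <- as.numeric(time)
  event <- as.integer(event)
  group <- as.integer(group)
  n <- length(time)
  if (length(event) != n || length(group) != n)
    stop("`time`, `event` and `group` must have the same length",
         call. = FALSE)
  if (sum(event) == 0L)
    stop("log-rank test requires at least one event", call. = FALSE)
  res <- .logrank_core(time, event, group)
  if (res$v <= 0)
    stop("log-rank variance is zero: groups have no at-risk overlap",
         call. = FALSE)
  res$hr <- exp((res$o1 - res$e1) / res$v)
  res
}

# Internal: no input checks, returns o1/e1/v/chisq. v == 0 signals a
# degenerate comparison that callers must handle.
.logrank_core <- function(time, event, group) {
  ord <- order(time, method = "radix")
  tt <- time[ord]
  is_ev <- event[ord] == 1L
  g1 <- group[ord] == 1L
  n <- length(tt)
  if (!any(is_ev)) return(list(chisq = NA_real_, o1 = 0, e1 = 0, v = 0))
  y1_all <- rev(cumsum(rev(g1)))             # group-1 at risk at each obs
  if (anyDuplicated(tt) == 0L) {
    # continuous times: one event per event time, (Y-d)/(Y-1) = 1
    idx <- which(is_ev)
    f <- y1_all[idx] / (n - idx + 1)
    e1 <- sum(f)
    v <- sum(f * (1 - f))
    o1 <- sum(g1[idx])
  } else {
    # grouped computation over distinct event times
    new_t <- !duplicated(tt)
    first_idx <- which(new_t)
    run_id <- cumsum(new_t)
    d <- rowsum(as.numeric(is_ev), run_id)[, 1L]
    d1 <- rowsum(as.numeric(is_ev & g1), run_id)[, 1L]
    keep <- d > 0
    y <- (n - first_idx + 1L)[keep]          # at risk (time >= t)
    y1 <- y1_all[first_idx][keep]
    d <- d[keep]
    e1 <- sum(d * y1 / y)
    v <- sum(d * (y1 / y) * (1 - y1 / y) * (y - d) / pmax(y - 1, 1))
    o1 <- sum(d1[keep])
  }
  chisq <- if (v > 0) (o1 - e1)^2 / v else NA_real_
  list(chisq = chisq, o1 = o1, e1 = e1, v = v)
}
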