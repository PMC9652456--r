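#' Operant schedule configuration
#'
#' Parameters of the head-fixed self-administration schedule: an active-lever
#' press that is reinforced triggers a tone cue and, after a short delay, a
#' sucrose delivery, and starts a timeout during which further presses have no
#' programmed consequence. The timeout interval is half-open
#' `[start, start + timeout_s)`, so a press landing exactly at the end of a
#' timeout counts as reinforced.
#'
#' A press is *reinforced* only when it actually delivers something: with both
#' `deliver_cue` and `deliver_sucrose` disabled (extinction) presses are
#' logged but never reinforced and no timeout is started. In reinstatement
#' (`deliver_cue = TRUE`, `deliver_sucrose = FALSE`) the timeout runs from cue
#' onset.
#'
#' @param timeout_s Timeout after each reinforced press, seconds.
#' @param cue_dur_s Tone cue duration, seconds.
#' @param sucrose_delay_s Press-to-sucrose-delivery interval, seconds (also
#'   the alignment gap used by the peri-event window).
#' @param sucrose_dur_s Sucrose delivery duration, seconds.
#' @param reward_cap Maximum sucrose deliveries per session, or `NULL` for
#'   uncapped. The acquisition schedule uses 10 (days 1-2), 20 (days 3-4) and
#'   40 (days 5 on).
#' @param deliver_cue,deliver_sucrose Logical switches for cue / sucrose
#'   delivery; both `TRUE` in acquisition, both `FALSE` in extinction, cue
#'   only in reinstatement.
#' @return An object of class `schedule_config`.
#' @export
schedule_config <- function(timeout_s = 20, cue_dur_s = 1.6,
                            sucrose_delay_s = 3, sucrose_dur_s = 2,
                            reward_cap = NULL,
                            deliver_cue = TRUE, deliver_sucrose = TRUE) {
  check_number(timeout_s, "timeout_s", min = 0)
  check_number(cue_dur_s, "cue_dur_s", min = 0)
  check_number(sucrose_delay_s, "sucrose_delay_s", min = 0)
  check_number(sucrose_dur_s, "sucrose_dur_s", min = 0)
  if (!is.null(reward_cap)) check_number(reward_cap, "reward_cap", min = 0)
  structure(list(timeout_s = timeout_s, cue_dur_s = cue_dur_s,
                 sucrose_delay_s = sucrose_delay_s,
                 sucrose_dur_s = sucrose_dur_s, reward_cap = reward_cap,
                 deliver_cue = isTRUE(deliver_cue),
                 deliver_sucrose = isTRUE(deliver_sucrose)),
            class = "schedule_config")
}

#' Default schedule for a behavioral phase
#'
#' @param phase One of `"acquisition"`, `"suppression_TMT"`,
#'   `"suppression_yohimbine"`, `"extinction"`, `"reinstatement"`.
#' @param reward_cap Cap on sucrose deliveries during acquisition (10, 20, 40
#'   or `NULL`); suppression sessions are uncapped, extinction and
#'   reinstatement deliver no sucrose.
#' @return A [schedule_config()].
#' @export
phase_schedule <- function(phase = c("acquisition", "suppression_TMT",
                                     "suppression_yohimbine", "extinction",
                                     "reinstatement"),
                           reward_cap = NULL) {
  phase <- match.arg(phase)
  switch(phase,
    acquisition = schedule_config(reward_cap = reward_cap),
    suppression_TMT = schedule_config(reward_cap = NULL),
    suppression_yohimbine = schedule_config(reward_cap = NULL),
    extinction = schedule_config(deliver_cue = FALSE, deliver_sucrose = FALSE),
    reinstatement = schedule_config(deliver_cue = TRUE, deliver_sucrose = FALSE)
  )
}

new_event_log <- function(events, duration_s, phase = "acquisition") {
  events <- events[order(events$time_s), , drop = FALSE]
  rownames(events) <- NULL
  structure(events, class = c("event_log", "data.frame"),
            duration_s = duration_s, phase = phase)
}

#' @export
print.event_log <- function(x, ...) {
  cat(sprintf("<event_log> phase=%s duration=%gs, %d events\n",
              attr(x, "phase"), attr(x, "duration_s"), nrow(x)))
  print.data.frame(head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("...\n")
  invisible(x)
}

#' Run press times through the operant schedule
#'
#' Walks active-lever presses in time order, maintaining timeout and
#' reward-cap state, and emits a full session event log: presses (both
#' levers, with a reinforced flag), cue onsets, sucrose deliveries and
#' timeout starts. Inactive-lever presses are logged but never reinforced.
#'
#' @param press_times_active,press_times_inactive Numeric vectors of press
#'   times in seconds (sorted internally, with a warning if unsorted).
#' @param cfg A [schedule_config()].
#' @param duration_s Session duration in seconds; presses must fall in
#'   `[0, duration_s]`.
#' @param phase Phase label stored on the log.
#' @return An `event_log` data frame with columns `time_s`, `event_type`
#'   (`press_active`, `press_inactive`, `cue_on`, `sucrose_on`,
#'   `timeout_start`), `lever` (`active`/`inactive`/`NA`) and `reinforced`.
#' @export
apply_schedule <- function(press_times_active, press_times_inactive = numeric(0),
                           cfg = schedule_config(), duration_s = 3600,
                           phase = "acquisition") {
  stopifnot(inherits(cfg, "schedule_config"))
  check_number(duration_s, "duration_s", min = 0, strict_min = TRUE)
  for (tv in list(press_times_active, press_times_inactive)) {
    if (length(tv) && (any(!is.finite(tv)) || any(tv < 0)))
      stop("press times must be finite and non-negative", call. = FALSE)
    if (length(tv) && any(tv > duration_s))
      stop("press times beyond session duration", call. = FALSE)
  }
  if (is.unsorted(press_times_active)) {
    warning("active press times unsorted; sorting")
    press_times_active <- sort(press_times_active)
  }
  if (is.unsorted(press_times_inactive)) {
    warning("inactive press times unsorted; sorting")
    press_times_inactive <- sort(press_times_inactive)
  }

  delivers <- cfg$deliver_cue || cfg$deliver_sucrose
  timeout_until <- -Inf
  rewards <- 0L
  time_s <- numeric(0); type <- character(0)
  lever <- character(0); reinf <- logical(0)
  add <- function(t, ty, lv, rf) {
    time_s[length(time_s) + 1L] <<- t
    type[length(type) + 1L] <<- ty
    lever[length(lever) + 1L] <<- lv
    reinf[length(reinf) + 1L] <<- rf
  }
  for (t in press_times_active) {
    cap_ok <- is.null(cfg$reward_cap) || !cfg$deliver_sucrose ||
      rewards < cfg$reward_cap
    # half-open timeout; ties at the boundary resolved with a 1-ns tolerance
    # so float arithmetic on timestamps cannot flip them
    reinforced <- delivers && t >= timeout_until - 1e-9 && cap_ok
    add(t, "press_active", "active", reinforced)
    if (reinforced) {
      if (cfg$deliver_cue) add(t, "cue_on", NA_character_, FALSE)
      if (cfg$deliver_sucrose) {
        add(t + cfg$sucrose_delay_s, "sucrose_on", NA_character_, FALSE)
        rewards <- rewards + 1L
      }
      add(t, "timeout_start", NA_character_, FALSE)
      timeout_until <- t + cfg$timeout_s
    }
  }
  for (t in press_times_inactive) add(t, "press_inactive", "inactive", FALSE)
  new_event_log(data.frame(time_s = time_s, event_type = type, lever = lever,
                           reinforced = reinf, stringsAsFactors = FALSE),
                duration_s = duration_s, phase = phase)
}

#' Tally a session event log
#'
#' @param log An `event_log`.
#' @return A list with counts `active_presses`, `inactive_presses`,
#'   `reinforced_presses`, `rewards_delivered`.
#' @export
summarize_session <- function(log) {
  stopifnot(inherits(log, "event_log"))
  list(
    active_presses = sum(log$event_type == "press_active"),
    inactive_presses = sum(log$event_type == "press_inactive"),
    reinforced_presses = sum(log$event_type == "press_active" & log$reinforced),
    rewards_delivered = sum(log$event_type == "sucrose_on")
  )
}

#' Evaluate the extinction criterion
#'
#' Extinction is declared when (1) at least `min_days` daily extinction
#' sessions have run and (2) at least 2 of the last 3 daily active-press
#' counts are at or below `frac` of the mean of the last two acquisition
#' sessions. Daily press counts stand in for pressing rate since sessions
#' are fixed length.
#'
#' @param extinction_daily_counts Integer vector of daily active-press counts
#'   during extinction, in session order.
#' @param acquisition_last2_counts Length-2 vector: active-press counts of
#'   the last two acquisition sessions.
#' @param frac Criterion fraction of the acquisition mean (default 0.20).
#' @param min_days Minimum number of extinction sessions (default 10).
#' @return A list: `met` (logical), `threshold`, `n_days`,
#'   `last3_below` (how many of the last 3 days met threshold), `reasons`
#'   (character).
#' @export
extinction_met <- function(extinction_daily_counts, acquisition_last2_counts,
                           frac = 0.20, min_days = 10) {
  if (length(acquisition_last2_counts) != 2)
    abort_config("acquisition_last2_counts must have length 2")
  acq_mean <- mean(acquisition_last2_counts)
  if (!is.finite(acq_mean) || acq_mean <= 0)
    stop("extinction criterion undefined: acquisition mean is not positive",
         call. = FALSE)
  n_days <- length(extinction_daily_counts)
  threshold <- frac * acq_mean
  last3 <- utils::tail(extinction_daily_counts, 3)
  below <- sum(last3 <= threshold)
  reasons <- character(0)
  if (n_days < min_days)
    reasons <- c(reasons, sprintf("only %d of %d required extinction days",
                                  n_days, min_days))
  if (below < 2)
    reasons <- c(reasons, sprintf(
      "%d of last 3 daily counts at or below threshold %.2f (need 2)",
      below, threshold))
  list(met = n_days >= min_days && below >= 2, threshold = threshold,
       n_days = n_days, last3_below = below, reasons = reasons)
}
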