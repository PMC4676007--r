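#' Unit quality control
#'
#' Sorted units with average rates below 4 or above 100 spikes/s are
#' excluded (strict inequalities: exactly 4 or 100 is kept). Units with
#' implausible inter-spike-interval distributions are operationalised as
#' those whose fraction of ISIs below the 2 ms refractory bound exceeds
#' 1.5%; this stand-in for sorting quality is configurable and flagged in
#' reports.
#'
#' @param train a [spike_train()].
#' @param analysis_duration seconds of data the rate is computed over, > 0.
#' @param rate_range acceptance band, spikes/s (default `c(4, 100)`).
#' @param refractory ISI plausibility bound, s (default 0.002).
#' @param max_violation_fraction maximum tolerated fraction of ISIs below
#'   `refractory` (default 0.015).
#' @return data.frame row: `unit_id`, `mean_rate`,
#'   `refractory_violation_fraction`, `decision`.
#' @export
unit_qc <- function(train, analysis_duration, rate_range = c(4, 100),
                    refractory = 0.002, max_violation_fraction = 0.015) {
  stopifnot(inherits(train, "spike_train"))
  if (analysis_duration <= 0)
    stop_plvnet("analysis_duration must be positive", "plvnet_bad_epoch")
  n <- length(train$timestamps)
  rate <- n / analysis_duration
  viol <- if (n < 2) 0 else mean(diff(train$timestamps) < refractory)
  decision <- if (rate < rate_range[1] || rate > rate_range[2])
    "rejected_rate"
  else if (viol > max_violation_fraction)
    "rejected_isi"
  else "accepted"
  data.frame(unit_id = train$unit_id, mean_rate = rate,
             refractory_violation_fraction = viol, decision = decision,
             stringsAsFactors = FALSE)
}

#' Firing rate in an epoch
#'
#' Count of timestamps in `[start, end)` divided by the epoch length.
#'
#' @param train a [spike_train()].
#' @param epoch `c(start, end)`, seconds, end > start.
#' @return spikes/s.
#' @export
firing_rate <- function(train, epoch) {
  stopifnot(inherits(train, "spike_train"))
  if (epoch[2] <= epoch[1])
    stop_plvnet("epoch must have positive length", "plvnet_bad_epoch")
  sum(train$timestamps >= epoch[1] & train$timestamps < epoch[2]) /
    (epoch[2] - epoch[1])
}

#' Evoked firing rate over a stimulus schedule
#'
#' Pools the 500 ms epochs after every pulse onset: total spikes across
#' epochs divided by total evoked time. With equal-length epochs this
#' equals the mean per-epoch rate.
#'
#' @param train a [spike_train()].
#' @param schedule a [stim_schedule()] with at least one couplet.
#' @param evoked_length seconds per epoch (default 0.5).
#' @return spikes/s.
#' @export
evoked_rate <- function(train, schedule, evoked_length = 0.5) {
  stopifnot(inherits(train, "spike_train"))
  if (!inherits(schedule, "stim_schedule") ||
      length(schedule$first_pulse_times) == 0)
    stop_plvnet("schedule must be non-empty", "plvnet_bad_schedule")
  on <- schedule_pulses(schedule)
  total <- sum(vapply(on, function(t0)
    sum(train$timestamps >= t0 & train$timestamps < t0 + evoked_length),
    numeric(1)))
  total / (length(on) * evoked_length)
}

#' Percent change of a treatment rate relative to a reference
#'
#' `100 * (treatment - reference) / reference`; undefined for a zero
#' reference.
#'
#' @param reference,treatment rates, spikes/s; `reference > 0`.
#' @return percent.
#' @export
percent_change <- function(reference, treatment) {
  if (any(reference <= 0))
    stop_plvnet("percent change undefined for non-positive reference",
                "plvnet_bad_sample")
  100 * (treatment - reference) / reference
}

#' Per-window firing-rate samples for one recording
#'
#' Rest epochs yield one rate per unit per non-overlapping window; tactile
#' sessions yield one rate per unit per 500 ms evoked epoch. These are the
#' FR sampling units consumed by the statistical layer.
#'
#' @param rec a [recording()] (QC-accepted units only, see [unit_qc()]).
#' @param epoch `c(start, end)` analysed epoch for rest windows; ignored
#'   when `evoked = TRUE`.
#' @param win_length rest window length, s (default 0.5).
#' @param evoked use the stimulus schedule's evoked epochs instead.
#' @return data.frame: `unit_id`, `region`, `window_start`, `rate`.
#' @export
rate_samples <- function(rec, epoch = NULL, win_length = 0.5,
                         evoked = FALSE) {
  stopifnot(inherits(rec, "recording"))
  if (evoked) {
    ep <- extract_evoked_epochs(rec)
    starts <- ep$start; len <- ep$end[1] - ep$start[1]
  } else {
    if (is.null(epoch)) epoch <- c(0, rec$session_meta$duration)
    ws <- split_windows(epoch[2] - epoch[1], win_length,
                        overlap_fraction = 0)
    starts <- epoch[1] + ws$starts; len <- win_length
  }
  do.call(rbind, lapply(rec$spike_trains, function(st) {
    counts <- vapply(starts, function(s0)
      sum(st$timestamps >= s0 & st$timestamps < s0 + len), numeric(1))
    data.frame(unit_id = st$unit_id, region = st$region,
               window_start = starts, rate = counts / len,
               stringsAsFactors = FALSE)
  }))
}

#' Rate summary table for one recording
#'
#' One row per unit x epoch type with the pooled rate, in the fixed column
#' order consumed downstream.
#'
#' @param rec a [recording()].
#' @param epoch rest epoch `c(start, end)`.
#' @return data.frame: `unit_id`, `region`, `group`, `condition`,
#'   `epoch_type`, `rate`.
#' @export
rate_table <- function(rec, epoch = NULL) {
  stopifnot(inherits(rec, "recording"))
  if (is.null(epoch)) epoch <- c(0, rec$session_meta$duration)
  meta <- rec$session_meta
  rest <- do.call(rbind, lapply(rec$spike_trains, function(st)
    data.frame(unit_id = st$unit_id, region = st$region, group = meta$group,
               condition = meta$condition, epoch_type = "rest",
               rate = firing_rate(st, epoch), stringsAsFactors = FALSE)))
  if (!is.null(rec$schedule) && length(rec$schedule$first_pulse_times)) {
    ev <- do.call(rbind, lapply(rec$spike_trains, function(st)
      data.frame(unit_id = st$unit_id, region = st$region,
                 group = meta$group, condition = meta$condition,
                 epoch_type = "evoked",
                 rate = evoked_rate(st, rec$schedule),
                 stringsAsFactors = FALSE)))
    rest <- rbind(rest, ev)
  }
  rest
}
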