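#' Zero-phase band-pass filtering of LFP signals
#'
#' Order-4 Butterworth band-pass applied forward and backward
#' (`signal::filtfilt`), so the filter contributes no phase shift and the
#' downstream instantaneous-phase estimates are undistorted. The default
#' band is 1-120 Hz, the analysis band for wide-band LFP.
#'
#' @param lfp numeric matrix (channels x samples) or vector.
#' @param fs sampling rate, Hz.
#' @param low,high band edges, Hz; `0 <= low < high < fs/2`. `low = 0`
#'   degenerates to a low-pass.
#' @param order Butterworth order per pass (default 4).
#' @return filtered signal, same shape as `lfp`.
#' @export
bandlimit_lfp <- function(lfp, fs, low = 1, high = 120, order = 4) {
  if (!(low >= 0 && low < high && high < fs / 2))
    stop_plvnet("band must satisfy 0 <= low < high < fs/2", "plvnet_bad_band")
  bf <- if (low > 0)
    signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  else
    signal::butter(order, high / (fs / 2), type = "low")
  apply_rows(lfp, function(x) signal::filtfilt(bf, x))
}

apply_rows <- function(x, f) {
  if (is.matrix(x)) {
    out <- t(apply(x, 1, f))
    dimnames(out) <- dimnames(x)
    out
  } else f(x)
}

#' Downsample LFP by integer decimation
#'
#' Zero-phase Butterworth anti-alias low-pass (cut-off at 80% of the target
#' Nyquist) followed by picking every q-th sample, q = `fs_in/fs_out`.
#' Output length is `floor(n_in * fs_out / fs_in)`.
#'
#' @param lfp matrix (channels x samples) or vector.
#' @param fs_in,fs_out sampling rates, Hz; `fs_in` must be an integer
#'   multiple of `fs_out`.
#' @return decimated signal.
#' @export
downsample_lfp <- function(lfp, fs_in, fs_out) {
  if (fs_out > fs_in)
    stop_plvnet("fs_out must not exceed fs_in", "plvnet_bad_band")
  q <- fs_in / fs_out
  if (abs(q - round(q)) > 1e-9)
    stop_plvnet("fs_in must be an integer multiple of fs_out",
                "plvnet_bad_band")
  q <- as.integer(round(q))
  if (q == 1L) return(lfp)
  bf <- signal::butter(4, 0.8 * (fs_out / 2) / (fs_in / 2), type = "low")
  dec <- function(x) {
    y <- signal::filtfilt(bf, x)
    y[seq(1L, by = q, length.out = floor(length(x) / q))]
  }
  apply_rows(lfp, dec)
}

#' Bin a spike train into a 1 ms binary sequence
#'
#' Bin b is 1 iff at least one timestamp falls in
#' `[start + (b-1)*0.001, start + b*0.001)`. The 1 ms bin width makes
#' multiple spikes per bin essentially impossible for plausible units;
#' should collisions occur they collapse to 1 with a warning.
#'
#' @param train a [spike_train()].
#' @param epoch numeric `c(start, end)` in seconds, half-open.
#' @param bin_width seconds, fixed at 0.001 by the analysis convention.
#' @return list with `bins` (0/1 integer vector of length
#'   `ceiling((end-start)/bin_width)`), `bin_width` and `t0`.
#' @export
bin_spikes <- function(train, epoch, bin_width = 0.001) {
  stopifnot(inherits(train, "spike_train"), length(epoch) == 2L,
            epoch[2] > epoch[1])
  nb <- as.integer(ceiling((epoch[2] - epoch[1]) / bin_width - 1e-9))
  ts <- train$timestamps
  ts <- ts[ts >= epoch[1] & ts < epoch[2]]
  bins <- integer(nb)
  if (length(ts)) {
    idx <- floor((ts - epoch[1]) / bin_width) + 1
    idx <- pmin(idx, nb)
    if (anyDuplicated(idx))
      warning(sprintf("unit %s: multiple spikes within one %g s bin collapsed",
                      train$unit_id, bin_width), call. = FALSE)
    bins[unique(idx)] <- 1L
  }
  list(bins = bins, bin_width = bin_width, t0 = epoch[1])
}

#' Segment an epoch into fixed-length overlapping windows
#'
#' Window starts lie at `k * length * (1 - overlap_fraction)`; the last
#' window fits entirely inside the epoch, so the count is
#' `floor((epoch_length - win_length)/step) + 1`. Analysis windows are
#' constrained to the 50-1000 ms range used throughout.
#'
#' @param epoch_length seconds.
#' @param win_length seconds, in \[0.050, 1.000\].
#' @param overlap_fraction in \[0, 1); default 0.5.
#' @return an object of class `window_set`: list with `length`,
#'   `overlap_fraction` and `starts` (window start times, s, relative to the
#'   epoch start).
#' @export
split_windows <- function(epoch_length, win_length = 0.5,
                          overlap_fraction = 0.5) {
  if (win_length < 0.050 - 1e-12 || win_length > 1.000 + 1e-12)
    stop_plvnet("win_length must lie in [0.050, 1.000] s", "plvnet_bad_window")
  if (overlap_fraction < 0 || overlap_fraction >= 1)
    stop_plvnet("overlap_fraction must lie in [0, 1)", "plvnet_bad_window")
  if (win_length > epoch_length + 1e-12)
    stop_plvnet("win_length exceeds epoch length", "plvnet_bad_window")
  step <- win_length * (1 - overlap_fraction)
  n <- floor((epoch_length - win_length) / step + 1e-9) + 1
  structure(list(length = win_length, overlap_fraction = overlap_fraction,
                 starts = (seq_len(n) - 1) * step),
            class = "window_set")
}

#' Trim a rest recording to its central epoch
#'
#' Rest sessions are analyzed excluding the first and last minute, so a
#' 10-minute recording yields an 8-minute epoch.
#'
#' @param rec a [recording()] with duration >= 180 s.
#' @return numeric `c(start, end)` = `c(60, duration - 60)`.
#' @export
trim_rest_epoch <- function(rec) {
  stopifnot(inherits(rec, "recording"))
  dur <- rec$session_meta$duration
  if (dur < 180)
    stop_plvnet("rest trimming requires duration >= 180 s", "plvnet_bad_epoch")
  c(60, dur - 60)
}

#' Evoked epochs: the first 500 ms after each stimulus pulse onset
#'
#' One epoch per pulse (both pulses of each couplet). Epochs from couplet
#' second pulses can overlap the first-pulse epoch when the couplet delay is
#' under 500 ms; they are kept as-is and flagged.
#'
#' @param rec a [recording()] with a non-empty schedule.
#' @param evoked_length seconds, default 0.5.
#' @return data.frame with columns `start`, `end`, `overlaps_previous`.
#' @export
extract_evoked_epochs <- function(rec, evoked_length = 0.5) {
  stopifnot(inherits(rec, "recording"))
  if (is.null(rec$schedule) || length(rec$schedule$first_pulse_times) == 0)
    stop_plvnet("recording has no stimulus schedule", "plvnet_bad_schedule")
  on <- schedule_pulses(rec$schedule)
  data.frame(start = on, end = on + evoked_length,
             overlaps_previous = c(FALSE, diff(on) < evoked_length))
}
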