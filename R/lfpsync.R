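#' Instantaneous phase via the analytic signal
#'
#' FFT-based quadrature construction: the analytic signal
#' `x(t) + i H(x)(t)` is obtained by zeroing negative frequencies (doubling
#' positive ones), and the phase is its argument, wrapped to (-pi, pi].
#' Inputs are assumed band-limited (see [bandlimit_lfp()]); the transform's
#' end effects mean the first and last few percent of samples should not be
#' trusted, which is why windowing downstream applies an edge guard.
#'
#' @param x numeric vector, LFP channel segment, length >= 64.
#' @param fs sampling rate, Hz.
#' @param source_channel optional channel label.
#' @return object of class `phase_series`: list with `phases` (rad, wrapped
#'   to (-pi, pi\]), `fs`, `source_channel`.
#' @export
analytic_phase <- function(x, fs, source_channel = NA) {
  if (length(x) < 64)
    stop_plvnet("segment must have at least 64 samples", "plvnet_bad_segment")
  if (sd(x) == 0)
    stop_plvnet("phase undefined for a constant segment", "plvnet_bad_segment")
  ph <- Arg(analytic_signal(x))
  # Arg returns (-pi, pi]; map -pi (possible from branch cut) onto pi
  ph[ph <= -pi] <- pi
  structure(list(phases = ph, fs = fs, source_channel = source_channel),
            class = "phase_series")
}

analytic_signal <- function(x) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  fft(X * h, inverse = TRUE) / n
}

phase_values <- function(p) {
  if (inherits(p, "phase_series")) p$phases else as.double(p)
}

#' Phase-locking value of two phase series
#'
#' `PLV = |(1/T) sum_t exp(i (phi_x(t) - phi_y(t)))|`: the modulus of the
#' time-averaged unit phasor of the phase difference. 1 means the phases are
#' locked (any constant offset), values near 0 mean independent phases; for
#' independent uniform phases the sampling floor is about `sqrt(pi)/(2
#' sqrt(T))`.
#'
#' @param x_phase,y_phase `phase_series` objects or plain phase vectors
#'   (rad), equal length T >= 25 (50 ms at 500 Hz).
#' @return PLV in \[0, 1\].
#' @export
plv <- function(x_phase, y_phase) {
  px <- phase_values(x_phase); py <- phase_values(y_phase)
  if (length(px) != length(py))
    stop_plvnet("phase series must have equal length", "plvnet_shape_mismatch")
  if (length(px) < 25)
    stop_plvnet("PLV requires at least 25 samples", "plvnet_bad_segment")
  min(1, Mod(mean(exp(1i * (px - py)))))
}

#' Pairwise PLV matrix of a multichannel window
#'
#' Evaluates every unordered channel pair once via the Gram matrix of unit
#' phasors; the result is symmetric with unit diagonal.
#'
#' @param x either an LFP matrix (channels x samples; phases are extracted
#'   per channel with [analytic_phase()]) or a matrix of phases when
#'   `is_phase = TRUE`.
#' @param fs sampling rate, Hz.
#' @param is_phase set `TRUE` when `x` already holds phases (rad).
#' @return symmetric PLV matrix with diagonal 1.
#' @export
pairwise_plv <- function(x, fs, is_phase = FALSE) {
  x <- as.matrix(x)
  if (nrow(x) < 2)
    stop_plvnet("need at least 2 channels", "plvnet_shape_mismatch")
  ph <- if (is_phase) x else
    t(apply(x, 1, function(ch) analytic_phase(ch, fs)$phases))
  plv_from_phases(ph)
}

plv_from_phases <- function(ph) {
  T <- ncol(ph)
  Z <- exp(1i * ph)
  M <- Mod(Z %*% Conj(t(Z))) / T
  M[M > 1] <- 1
  # the Gram product's (i,j) and (j,i) dot products round differently;
  # mirror the upper triangle so symmetry is bit-exact
  M[lower.tri(M)] <- t(M)[lower.tri(M)]
  diag(M) <- 1
  M
}

#' Windowed PLV matrices over an epoch
#'
#' Phase is extracted once per channel over the whole epoch (avoiding
#' per-window Hilbert end effects), the first and last `edge_guard` fraction
#' of samples are excluded, and the remaining phase samples are sliced into
#' windows, each yielding one PLV matrix. Channels that fail phase
#' extraction abort with a classed error naming the channel.
#'
#' @param lfp band-limited LFP matrix, channels x samples.
#' @param fs sampling rate, Hz.
#' @param win_length window length, s (default 0.5).
#' @param overlap overlap fraction in \[0, 1) (default 0.5); ignored when
#'   `starts` is given.
#' @param starts optional explicit window start times (s, relative to the
#'   epoch start), e.g. stimulus onsets; windows falling outside the guarded
#'   region are dropped.
#' @param edge_guard fraction of samples excluded at each end (default
#'   0.05).
#' @return 3-D array channels x channels x windows, with attribute
#'   `window_starts` (s).
#' @export
windowed_plv <- function(lfp, fs, win_length = 0.5, overlap = 0.5,
                         starts = NULL, edge_guard = 0.05) {
  lfp <- as.matrix(lfp)
  n <- ncol(lfp)
  ph <- matrix(0, nrow(lfp), n)
  for (c in seq_len(nrow(lfp))) {
    p <- tryCatch(analytic_phase(lfp[c, ], fs),
                  error = function(e) stop_plvnet(
                    sprintf("channel %d: %s", c, conditionMessage(e)),
                    "plvnet_bad_segment"))
    ph[c, ] <- p$phases
  }
  guard <- floor(edge_guard * n)
  lo <- guard + 1
  hi <- n - guard
  T <- as.integer(round(win_length * fs))
  if (is.null(starts)) {
    usable <- (hi - lo + 1) / fs
    ws <- split_windows(usable, win_length, overlap)
    starts <- (lo - 1) / fs + ws$starts
  } else {
    starts <- starts[floor(starts * fs) + 1 >= lo &
                       floor(starts * fs) + T <= hi]
  }
  i0 <- floor(starts * fs) + 1
  keep <- i0 >= 1 & (i0 + T - 1) <= n
  i0 <- i0[keep]; starts <- starts[keep]
  out <- array(0, c(nrow(lfp), nrow(lfp), length(i0)))
  for (w in seq_along(i0))
    out[, , w] <- plv_from_phases(ph[, i0[w]:(i0[w] + T - 1), drop = FALSE])
  attr(out, "window_starts") <- starts
  out
}
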