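#' Construct a sorted-unit spike train
#'
#' @param unit_id character or integer unit identifier.
#' @param channel recording channel the unit was sorted from.
#' @param region region label, `"VPL"` or `"S1"`.
#' @param timestamps spike times in seconds, sorted strictly increasing,
#'   all non-negative.
#' @param qc_status one of `"pending"`, `"accepted"`, `"rejected_rate"`,
#'   `"rejected_isi"`.
#' @return an object of class `spike_train`.
#' @export
spike_train <- function(unit_id, channel, region, timestamps,
                        qc_status = "pending") {
  timestamps <- as.double(timestamps)
  if (length(timestamps) > 0) {
    if (any(!is.finite(timestamps)) || any(timestamps < 0))
      stop_plvnet("spike timestamps must be finite and non-negative",
                  "plvnet_bad_spikes")
    if (is.unsorted(timestamps, strictly = TRUE))
      stop_plvnet("spike timestamps must be sorted strictly increasing",
                  "plvnet_bad_spikes")
  }
  qc_status <- match.arg(qc_status,
                         c("pending", "accepted", "rejected_rate", "rejected_isi"))
  structure(list(unit_id = unit_id, channel = channel, region = region,
                 timestamps = timestamps, qc_status = qc_status),
            class = "spike_train")
}

#' Construct a couplet stimulus schedule
#'
#' Pulses occur in couplets: first pulses on a regular grid, each second
#' pulse trailing its first by a delay in \[0.150, 0.250\] s. Pulse width is
#' metadata only (the 5 ms pressure pulse of the tactile protocol).
#'
#' @param first_pulse_times seconds, sorted.
#' @param second_pulse_times seconds, same length as `first_pulse_times`.
#' @param pulse_width seconds, default 0.005.
#' @return an object of class `stim_schedule`.
#' @export
stim_schedule <- function(first_pulse_times, second_pulse_times,
                          pulse_width = 0.005) {
  first_pulse_times <- as.double(first_pulse_times)
  second_pulse_times <- as.double(second_pulse_times)
  if (length(first_pulse_times) != length(second_pulse_times))
    stop_plvnet("first and second pulse time vectors must have equal length",
                "plvnet_bad_schedule")
  if (length(first_pulse_times) > 0) {
    d <- second_pulse_times - first_pulse_times
    if (any(d < 0.150 - 1e-12) || any(d > 0.250 + 1e-12))
      stop_plvnet("second-pulse delays must lie in [0.150, 0.250] s",
                  "plvnet_bad_schedule")
  }
  structure(list(first_pulse_times = first_pulse_times,
                 second_pulse_times = second_pulse_times,
                 pulse_width = as.double(pulse_width)),
            class = "stim_schedule")
}

#' All pulse onsets of a schedule, sorted
#' @param schedule a [stim_schedule()].
#' @return numeric vector of onset times (s).
#' @export
schedule_pulses <- function(schedule) {
  stopifnot(inherits(schedule, "stim_schedule"))
  sort(c(schedule$first_pulse_times, schedule$second_pulse_times))
}

#' Construct a Recording
#'
#' One session: an LFP matrix, sorted spike trains, an optional stimulus
#' schedule, per-channel metadata (region and position in the 3 x 3
#' electrode matrix) and session metadata (group, condition, duration).
#'
#' @param lfp numeric matrix, channels x samples, microvolts.
#' @param fs_lfp sampling rate in Hz.
#' @param spike_trains list of [spike_train()] objects.
#' @param schedule a [stim_schedule()] or `NULL` for rest sessions.
#' @param channel_meta data.frame with columns `channel`, `region`,
#'   `row`, `col`; one row per LFP channel.
#' @param session_meta list with elements `group` (`"CR"` or `"CCI"`),
#'   `condition` (`"rest"`, `"tactile"`, `"reac_rest"`, `"reac_tactile"`)
#'   and `duration` (seconds).
#' @return an object of class `recording`.
#' @export
recording <- function(lfp, fs_lfp, spike_trains = list(), schedule = NULL,
                      channel_meta, session_meta) {
  lfp <- as.matrix(lfp)
  rec <- structure(list(lfp = lfp, fs_lfp = as.double(fs_lfp),
                        spike_trains = spike_trains, schedule = schedule,
                        channel_meta = channel_meta,
                        session_meta = session_meta),
                   class = "recording")
  validate_recording(rec)
  rec
}

#' Validate a Recording's invariants
#'
#' Checks: finite LFP, positive sampling rate, channel metadata matching the
#' LFP row count, spike timestamps inside the session, well-formed schedule.
#'
#' @param rec a [recording()].
#' @return `rec`, invisibly; signals a classed error on violation.
#' @export
validate_recording <- function(rec) {
  stopifnot(inherits(rec, "recording"))
  if (!all(is.finite(rec$lfp)))
    stop_plvnet("LFP contains non-finite values", "plvnet_bad_lfp")
  if (!is.finite(rec$fs_lfp) || rec$fs_lfp <= 0)
    stop_plvnet("fs_lfp must be positive", "plvnet_bad_lfp")
  if (nrow(rec$channel_meta) != nrow(rec$lfp))
    stop_plvnet("channel_meta rows must match LFP channel count",
                "plvnet_shape_mismatch")
  dur <- rec$session_meta$duration
  for (st in rec$spike_trains) {
    stopifnot(inherits(st, "spike_train"))
    if (length(st$timestamps) && max(st$timestamps) >= dur)
      stop_plvnet(sprintf("unit %s has timestamps beyond session duration",
                          st$unit_id), "plvnet_bad_spikes")
  }
  if (!is.null(rec$schedule)) stopifnot(inherits(rec$schedule, "stim_schedule"))
  invisible(rec)
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %s/%s: %d channels x %d samples @ %g Hz, %d units, %s\n",
              x$session_meta$group, x$session_meta$condition,
              nrow(x$lfp), ncol(x$lfp), x$fs_lfp, length(x$spike_trains),
              if (is.null(x$schedule)) "no stimuli" else
                sprintf("%d couplets", length(x$schedule$first_pulse_times))))
  invisible(x)
}

fmt_num <- function(x) sprintf("%.17g", x)

#' Write a Recording bundle to disk
#'
#' One directory per recording: `lfp.bin` (flat little-endian float64,
#' channel-major) with a `lfp.json` sidecar (shape, dtype, sampling rate,
#' units), `spikes.tsv` and `stimuli.tsv` event files, and `meta.json`.
#' Event times are written with 17 significant digits so the text round-trip
#' is bit-exact for doubles.
#'
#' @param rec a [recording()].
#' @param path directory to create/overwrite.
#' @return `path`, invisibly.
#' @seealso [read_recording()]
#' @export
write_recording <- function(rec, path) {
  validate_recording(rec)
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  con <- file(file.path(path, "lfp.bin"), "wb")
  on.exit(close(con), add = TRUE)
  # channel-major: each channel's samples contiguous
  writeBin(as.double(t(rec$lfp)), con, size = 8, endian = "little")
  jsonlite::write_json(
    list(n_channels = nrow(rec$lfp), n_samples = ncol(rec$lfp),
         dtype = "float64", byte_order = "little", layout = "channel_major",
         fs_hz = rec$fs_lfp, units = "uV"),
    file.path(path, "lfp.json"), auto_unbox = TRUE, digits = NA)

  sp <- do.call(rbind, lapply(rec$spike_trains, function(st) {
    if (length(st$timestamps) == 0) return(NULL)
    data.frame(unit_id = st$unit_id, channel = st$channel, region = st$region,
               time_s = fmt_num(st$timestamps))
  }))
  if (is.null(sp))
    sp <- data.frame(unit_id = character(), channel = integer(),
                     region = character(), time_s = character())
  write.table(sp, file.path(path, "spikes.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)

  if (!is.null(rec$schedule)) {
    nc <- length(rec$schedule$first_pulse_times)
    stim <- data.frame(
      couplet_idx = rep(seq_len(nc), each = 2),
      pulse_idx = rep(1:2, nc),
      time_s = fmt_num(as.vector(rbind(rec$schedule$first_pulse_times,
                                       rec$schedule$second_pulse_times))))
  } else {
    stim <- data.frame(couplet_idx = integer(), pulse_idx = integer(),
                       time_s = character())
  }
  write.table(stim, file.path(path, "stimuli.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)

  units <- lapply(rec$spike_trains, function(st)
    list(unit_id = st$unit_id, channel = st$channel, region = st$region,
         qc_status = st$qc_status))
  jsonlite::write_json(
    list(group = rec$session_meta$group,
         condition = rec$session_meta$condition,
         duration = rec$session_meta$duration,
         pulse_width = if (is.null(rec$schedule)) NULL else
           rec$schedule$pulse_width,
         channel_meta = rec$channel_meta,
         units = units),
    file.path(path, "meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a Recording bundle from disk
#'
#' Inverse of [write_recording()]; the round-trip is lossless. Malformed
#' bundles (shape mismatches, non-monotone timestamps, missing files) are
#' rejected with classed errors.
#'
#' @param path bundle directory.
#' @return a [recording()].
#' @export
read_recording <- function(path) {
  need <- c("lfp.bin", "lfp.json", "spikes.tsv", "stimuli.tsv", "meta.json")
  missing <- need[!file.exists(file.path(path, need))]
  if (length(missing))
    stop_plvnet(paste("bundle is missing:", paste(missing, collapse = ", ")),
                "plvnet_bad_bundle")
  side <- jsonlite::read_json(file.path(path, "lfp.json"), simplifyVector = TRUE)
  nch <- side$n_channels; ns <- side$n_samples
  sz <- file.info(file.path(path, "lfp.bin"))$size
  if (sz != nch * ns * 8)
    stop_plvnet(sprintf(
      "lfp.bin has %d bytes but sidecar declares %d channels x %d samples",
      sz, nch, ns), "plvnet_shape_mismatch")
  con <- file(file.path(path, "lfp.bin"), "rb")
  on.exit(close(con), add = TRUE)
  x <- readBin(con, "double", n = nch * ns, size = 8, endian = "little")
  lfp <- t(matrix(x, nrow = ns, ncol = nch))

  meta <- jsonlite::read_json(file.path(path, "meta.json"), simplifyVector = TRUE)
  channel_meta <- as.data.frame(meta$channel_meta)
  if (nrow(channel_meta) != nch)
    stop_plvnet("channel_meta rows do not match declared channel count",
                "plvnet_shape_mismatch")

  sp <- utils::read.delim(file.path(path, "spikes.tsv"),
                          colClasses = c("character", "integer", "character",
                                         "character"))
  units <- meta$units
  if (is.data.frame(units)) units <- split(units, seq_len(nrow(units)))
  spike_trains <- lapply(units, function(u) {
    ts <- as.double(sp$time_s[sp$unit_id == u$unit_id])
    if (length(ts) && is.unsorted(ts, strictly = TRUE))
      stop_plvnet(sprintf("unit %s has non-monotone timestamps", u$unit_id),
                  "plvnet_bad_spikes")
    spike_train(u$unit_id, u$channel, u$region, ts, u$qc_status)
  })
  names(spike_trains) <- NULL

  stim <- utils::read.delim(file.path(path, "stimuli.tsv"),
                            colClasses = c("integer", "integer", "character"))
  schedule <- NULL
  if (nrow(stim) > 0) {
    schedule <- stim_schedule(
      as.double(stim$time_s[stim$pulse_idx == 1]),
      as.double(stim$time_s[stim$pulse_idx == 2]),
      pulse_width = meta$pulse_width %||% 0.005)
  }
  recording(lfp, as.double(side$fs_hz), spike_trains, schedule, channel_meta,
            list(group = meta$group, condition = meta$condition,
                 duration = as.double(meta$duration)))
}
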