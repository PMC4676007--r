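#' Synthetic-recording generator configuration
#'
#' The generator is a stochastic Kuramoto system read out as noisy cosine
#' LFPs, plus rate-modulated Poisson spike trains: exactly the statistical
#' structure the phase-locking analysis parameterises, which makes parameter
#' recovery well posed. Channels are laid out as one 3 x 3 electrode matrix
#' per region.
#'
#' @param n_channels_per_region channels (= oscillators = units) per region.
#' @param regions region labels, default `c("VPL", "S1")`.
#' @param duration session length, seconds.
#' @param fs sampling rate, Hz (default 500, the analysis rate).
#' @param natural_freqs oscillator natural frequencies, Hz; default drawn
#'   once from U(8, 30) using `seed` (inside the 1-120 Hz analysis band and
#'   below Nyquist).
#' @param coupling symmetric non-negative coupling matrix, rad/s, zero
#'   diagonal. Default: within-region `k_within`, between-region
#'   `k_between`.
#' @param k_within,k_between defaults used to build `coupling` when it is
#'   not supplied, rad/s.
#' @param phase_noise_sd phase diffusion, rad/sqrt(s).
#' @param amplitude cosine readout amplitude per channel, microvolts
#'   (recycled).
#' @param obs_noise_sd additive white observation noise, microvolts.
#' @param base_rates unit base firing rates, spikes/s (one unit per
#'   channel); default drawn once from U(8, 30) using `seed`, inside the
#'   4-100 spikes/s acceptance band.
#' @param stim_rate_gain multiplicative rate gain inside evoked epochs
#'   (>= 0), default 2.
#' @param seed integer master seed; spawns per-stream sub-seeds.
#' @return an object of class `synth_config`.
#' @export
synth_config <- function(n_channels_per_region = 9,
                         regions = c("VPL", "S1"),
                         duration = 600, fs = 500,
                         natural_freqs = NULL, coupling = NULL,
                         k_within = 1.0, k_between = 0.5,
                         phase_noise_sd = 2.5,
                         amplitude = 40, obs_noise_sd = 15,
                         base_rates = NULL, stim_rate_gain = 2,
                         seed = 1L) {
  m <- n_channels_per_region * length(regions)
  if (is.null(natural_freqs)) {
    set.seed(derive_seed(seed, 101))
    natural_freqs <- runif(m, 8, 30)
  }
  if (is.null(coupling)) {
    blk <- rep(seq_along(regions), each = n_channels_per_region)
    coupling <- matrix(k_between, m, m)
    for (b in seq_along(regions))
      coupling[blk == b, blk == b] <- k_within
    diag(coupling) <- 0
  }
  if (is.null(base_rates)) {
    set.seed(derive_seed(seed, 102))
    base_rates <- runif(m, 8, 30)
  }
  cfg <- structure(list(
    n_channels_per_region = n_channels_per_region, regions = regions,
    duration = as.double(duration), fs = as.double(fs),
    natural_freqs = as.double(natural_freqs), coupling = coupling,
    phase_noise_sd = as.double(phase_noise_sd),
    amplitude = rep_len(as.double(amplitude), m),
    obs_noise_sd = as.double(obs_noise_sd),
    base_rates = as.double(base_rates),
    stim_rate_gain = as.double(stim_rate_gain),
    evoked_coupling_multiplier = 1.0,
    seed = as.integer(seed)), class = "synth_config")
  validate_synth_config(cfg)
  cfg
}

#' @export
print.synth_config <- function(x, ...) {
  cat(sprintf("<synth_config> %d osc (%s), %g s @ %g Hz, seed %d\n",
              length(x$natural_freqs), paste(x$regions, collapse = "+"),
              x$duration, x$fs, x$seed))
  invisible(x)
}

#' Validate a synth_config
#'
#' Enforces: symmetric non-negative coupling with zero diagonal,
#' `fs > 2 * max(natural_freqs)`, positive duration, non-negative rates and
#' finite parameters.
#'
#' @param cfg a [synth_config()].
#' @return `cfg`, invisibly.
#' @export
validate_synth_config <- function(cfg) {
  m <- length(cfg$natural_freqs)
  num <- c(cfg$duration, cfg$fs, cfg$natural_freqs, cfg$coupling,
           cfg$phase_noise_sd, cfg$amplitude, cfg$obs_noise_sd,
           cfg$base_rates, cfg$stim_rate_gain)
  if (any(!is.finite(num)))
    stop_plvnet("synth_config has non-finite parameters", "plvnet_bad_config")
  K <- cfg$coupling
  if (!is.matrix(K) || nrow(K) != m || ncol(K) != m)
    stop_plvnet("coupling must be an m x m matrix", "plvnet_bad_config")
  if (any(K < 0) || any(abs(K - t(K)) > 1e-12) || any(diag(K) != 0))
    stop_plvnet("coupling must be symmetric, non-negative, zero diagonal",
                "plvnet_bad_config")
  if (cfg$duration <= 0)
    stop_plvnet("duration must be positive", "plvnet_bad_config")
  if (cfg$fs <= 2 * max(cfg$natural_freqs))
    stop_plvnet("fs must exceed twice the largest natural frequency",
                "plvnet_bad_config")
  if (any(cfg$base_rates < 0) || cfg$stim_rate_gain < 0)
    stop_plvnet("rates and gains must be non-negative", "plvnet_bad_config")
  invisible(cfg)
}

#' The thalamocortical study preset
#'
#' [synth_config()] specialised to the regime the pipeline simulates: 9
#' channels per region (VPL, S1), narrowband per-channel natural
#' frequencies U(9, 13) Hz emulating a shared mu-like rhythm (pairwise
#' coupling of a few rad/s can only express synchrony differences when
#' detuning is comparable to coupling), block-structured coupling stronger
#' within than between regions, and unit rates U(8, 30) spikes/s inside the
#' quality-control acceptance band.
#'
#' @param duration seconds.
#' @param seed integer master seed.
#' @param ... overrides passed to [synth_config()].
#' @return a `synth_config`.
#' @export
thalamocortical_config <- function(duration = 600, seed = 1L, ...) {
  set.seed(derive_seed(seed, 103))
  freqs <- runif(18, 9, 13)
  synth_config(n_channels_per_region = 9, regions = c("VPL", "S1"),
               duration = duration, natural_freqs = freqs,
               k_within = 1.0, k_between = 0.5, phase_noise_sd = 2.5,
               amplitude = 40, obs_noise_sd = 15, stim_rate_gain = 2,
               seed = seed, ...)
}

#' The group x condition preset table
#'
#' Eight cells (CR/CCI x rest/tactile/reac_rest/reac_tactile) encoding the
#' effect directions of the study design: chronic pain (CCI) raises resting
#' synchrony (coupling x1.3); tactile stimulation boosts coupling during
#' evoked epochs (x2); REAC application raises synchrony (coupling x1.5 on
#' the group base) and firing rates by the four printed percent changes
#' (x1.43 CR rest, x1.93 CCI rest, x1.09 CR tactile, x1.41 CCI tactile).
#' Synchrony multipliers are calibration choices (the source reports
#' directions and significance, not PLV effect sizes); rate multipliers are
#' the reported percent increments.
#'
#' @return data.frame with columns `group`, `condition`,
#'   `coupling_multiplier`, `rate_multiplier`, `evoked_coupling_multiplier`.
#' @export
condition_presets <- function() {
  data.frame(
    group = rep(c("CR", "CCI"), times = 4),
    condition = rep(c("rest", "tactile", "reac_rest", "reac_tactile"),
                    each = 2),
    coupling_multiplier = c(1.00, 1.30, 1.00, 1.30, 1.50, 1.95, 1.50, 1.95),
    rate_multiplier     = c(1.00, 1.00, 1.00, 1.00, 1.43, 1.93, 1.09, 1.41),
    evoked_coupling_multiplier = c(1, 1, 2, 2, 1, 1, 2, 2),
    stringsAsFactors = FALSE)
}

#' Apply a group x condition preset to a configuration
#'
#' Returns a new config with the coupling matrix scaled by the preset's
#' `coupling_multiplier`, base rates scaled by `rate_multiplier`, and the
#' `evoked_coupling_multiplier` recorded for use inside evoked epochs.
#'
#' @param config a [synth_config()].
#' @param group `"CR"` or `"CCI"`.
#' @param condition one of `"rest"`, `"tactile"`, `"reac_rest"`,
#'   `"reac_tactile"`.
#' @param preset_table preset table, default [condition_presets()].
#' @return a new `synth_config`.
#' @export
apply_condition <- function(config, group, condition,
                            preset_table = condition_presets()) {
  row <- preset_table[preset_table$group == group &
                        preset_table$condition == condition, ]
  if (nrow(row) != 1)
    stop_plvnet(sprintf("unknown preset: %s/%s", group, condition),
                "plvnet_bad_preset")
  if (any(c(row$coupling_multiplier, row$rate_multiplier,
            row$evoked_coupling_multiplier) <= 0))
    stop_plvnet("preset multipliers must be positive", "plvnet_bad_preset")
  out <- config
  out$coupling <- config$coupling * row$coupling_multiplier
  out$base_rates <- config$base_rates * row$rate_multiplier
  out$evoked_coupling_multiplier <- row$evoked_coupling_multiplier
  validate_synth_config(out)
  out
}

#' Simulate coupled-oscillator phase trajectories
#'
#' Euler-Maruyama integration of stochastic Kuramoto dynamics
#' `dphi_i = omega_i dt + sum_j K_ij sin(phi_j - phi_i) dt + sigma dW_i`
#' at step `dt = 1/fs`. Phases are returned unwrapped (cumulative), one row
#' per oscillator. Deterministic given the seed.
#'
#' @param config a [synth_config()].
#' @param epoch seconds to simulate (default `config$duration`).
#' @param coupling_gain optional per-sample multiplier on the whole coupling
#'   matrix (length `round(epoch*fs)`), used to realise evoked coupling
#'   boosts; default 1 everywhere.
#' @param seed integer; default derived from `config$seed`.
#' @param dt integration step, seconds; must not exceed `1/fs`.
#' @return matrix oscillators x samples of unwrapped phases (rad).
#' @export
simulate_phases <- function(config, epoch = config$duration,
                            coupling_gain = NULL, seed = NULL, dt = NULL) {
  validate_synth_config(config)
  fs <- config$fs
  dt <- dt %||% (1 / fs)
  if (dt > 1 / fs + 1e-12)
    stop_plvnet("integration step must not exceed 1/fs", "plvnet_bad_config")
  n <- as.integer(round(epoch * fs))
  m <- length(config$natural_freqs)
  if (!is.null(coupling_gain) && length(coupling_gain) != n)
    stop_plvnet("coupling_gain must have one value per sample",
                "plvnet_bad_config")
  omega <- 2 * pi * config$natural_freqs
  K <- config$coupling
  coupled <- any(K > 0)
  sq <- config$phase_noise_sd * sqrt(dt)
  set.seed(seed %||% derive_seed(config$seed, 1))
  th <- runif(m, -pi, pi)
  phi <- matrix(0, m, n)
  for (t in seq_len(n)) {
    if (coupled) {
      s <- sin(th); cs <- cos(th)
      g <- if (is.null(coupling_gain)) 1 else coupling_gain[t]
      drift <- omega + g * (cs * as.vector(K %*% s) - s * as.vector(K %*% cs))
    } else drift <- omega
    th <- th + drift * dt + if (sq > 0) sq * rnorm(m) else 0
    phi[, t] <- th
  }
  phi
}

#' Cosine readout of phase trajectories as LFP
#'
#' `x_c(t) = A_c cos(phi_c(t)) + eps_c(t)` with
#' `eps ~ N(0, obs_noise_sd^2)`, sampled at `config$fs`.
#'
#' @param phases matrix oscillators x samples (rad).
#' @param config a [synth_config()].
#' @param seed integer; default derived from `config$seed`.
#' @return LFP matrix channels x samples, microvolts.
#' @export
synth_lfp <- function(phases, config, seed = NULL) {
  if (any(!is.finite(phases)))
    stop_plvnet("phases must be finite", "plvnet_bad_config")
  m <- nrow(phases)
  if (m != length(config$amplitude))
    stop_plvnet("phases rows must match configured channels",
                "plvnet_shape_mismatch")
  x <- config$amplitude * cos(phases)
  if (config$obs_noise_sd > 0) {
    set.seed(seed %||% derive_seed(config$seed, 2))
    x <- x + matrix(rnorm(length(x), 0, config$obs_noise_sd),
                    nrow = m)
  }
  x
}

#' Generate an inhomogeneous Poisson spike train by thinning
#'
#' Candidates are drawn from a homogeneous Poisson process at the maximum
#' (dead-time-compensated) intensity, thinned to the per-sample target
#' intensity, then pruned to enforce an absolute refractory period. The
#' thinning intensity uses the dead-time compensation
#' `lambda*(t) = r(t) / (1 - r(t) * refractory)` so the realised
#' post-refractory rate equals the requested rate.
#'
#' @param rate_profile spikes/s per sample (non-negative), at `fs`.
#' @param duration seconds; `length(rate_profile) = round(duration*fs)`.
#' @param seed integer seed.
#' @param fs sampling rate of `rate_profile`, Hz.
#' @param refractory absolute refractory period, seconds (default 0.002).
#' @param unit_id,channel,region labels attached to the result.
#' @return a [spike_train()].
#' @export
synth_spikes <- function(rate_profile, duration, seed, fs = 500,
                         refractory = 0.002, unit_id = "u1", channel = 1L,
                         region = "VPL") {
  if (any(rate_profile < 0) || any(!is.finite(rate_profile)))
    stop_plvnet("rate_profile must be finite and non-negative",
                "plvnet_bad_config")
  if (max(rate_profile) * refractory >= 1)
    stop_plvnet("max rate x refractory must be < 1 (thinning invalid)",
                "plvnet_bad_config")
  n <- as.integer(round(duration * fs))
  if (length(rate_profile) == 1L) rate_profile <- rep(rate_profile, n)
  if (length(rate_profile) != n)
    stop_plvnet("rate_profile must have one value per sample",
                "plvnet_shape_mismatch")
  lam <- rate_profile / (1 - rate_profile * refractory)
  lam_max <- max(lam)
  if (lam_max == 0)
    return(spike_train(unit_id, channel, region, numeric(0)))
  set.seed(seed)
  n_cand <- rpois(1, lam_max * duration)
  cand <- sort(runif(n_cand, 0, duration))
  idx <- pmin(floor(cand * fs) + 1, n)
  keep <- runif(n_cand) < lam[idx] / lam_max
  ts <- cand[keep]
  if (length(ts) > 1) {
    out <- numeric(length(ts)); k <- 0L; last <- -Inf
    for (t in ts) {
      if (t - last >= refractory) { k <- k + 1L; out[k] <- t; last <- t }
    }
    ts <- out[seq_len(k)]
  }
  spike_train(unit_id, channel, region, ts)
}

#' Generate the couplet tactile-stimulation schedule
#'
#' First pulses every 500 ms from t = 0; each second pulse follows its first
#' by a uniform random delay in \[150, 250\] ms; 5 ms pulse width recorded as
#' metadata.
#'
#' @param duration seconds, >= 0.5.
#' @param seed integer seed.
#' @return a [stim_schedule()] with `floor(duration/0.5)` couplets.
#' @export
synth_stimulus_schedule <- function(duration, seed) {
  if (duration < 0.5)
    stop_plvnet("duration must be at least 0.5 s", "plvnet_bad_schedule")
  nc <- as.integer(floor(duration / 0.5 + 1e-9))
  first <- (seq_len(nc) - 1) * 0.5
  set.seed(seed)
  second <- first + runif(nc, 0.150, 0.250)
  stim_schedule(first, second)
}

#' Generate one full synthetic recording for a group x condition cell
#'
#' Applies the condition preset, simulates Kuramoto phases (with the evoked
#' coupling boost active during the 500 ms after each pulse onset, for
#' tactile conditions), reads them out as noisy LFP, draws one Poisson unit
#' per channel (with the evoked rate gain in evoked epochs), and assembles a
#' [recording()]. Bit-reproducible for a given config and seed.
#'
#' @param config a [synth_config()]; its `seed` drives all streams unless
#'   `seed` is given.
#' @param group,condition preset cell; the preset is applied to `config`.
#' @param preset_table default [condition_presets()].
#' @param seed optional master seed override.
#' @return list with elements `recording` (a [recording()]) and
#'   `ground_truth` (realised coupling matrix, region block labels, true
#'   unit rates) for recovery tests.
#' @export
synth_recording <- function(config, group = "CR", condition = "rest",
                            preset_table = condition_presets(), seed = NULL) {
  seed <- seed %||% config$seed
  cfg <- apply_condition(config, group, condition, preset_table)
  fs <- cfg$fs
  dur <- cfg$duration
  n <- as.integer(round(dur * fs))
  m <- length(cfg$natural_freqs)
  tactile <- condition %in% c("tactile", "reac_tactile")

  schedule <- NULL
  gain <- NULL
  evoked_mask <- rep(FALSE, n)
  if (tactile) {
    schedule <- synth_stimulus_schedule(dur, derive_seed(seed, 4))
    on <- schedule_pulses(schedule)
    for (t0 in on) {
      i0 <- floor(t0 * fs) + 1
      i1 <- min(n, ceiling((t0 + 0.5) * fs))
      evoked_mask[i0:i1] <- TRUE
    }
    gain <- ifelse(evoked_mask, cfg$evoked_coupling_multiplier, 1)
  }

  phases <- simulate_phases(cfg, epoch = dur, coupling_gain = gain,
                            seed = derive_seed(seed, 1))
  lfp <- synth_lfp(phases, cfg, seed = derive_seed(seed, 2))

  blk <- rep(cfg$regions, each = cfg$n_channels_per_region)
  rc <- expand.grid(row = 1:3, col = 1:3)[seq_len(cfg$n_channels_per_region), ]
  channel_meta <- data.frame(channel = seq_len(m), region = blk,
                             row = rep(rc$row, length(cfg$regions)),
                             col = rep(rc$col, length(cfg$regions)),
                             stringsAsFactors = FALSE)

  spike_trains <- vector("list", m)
  for (u in seq_len(m)) {
    prof <- rep(cfg$base_rates[u], n)
    if (tactile) prof[evoked_mask] <- prof[evoked_mask] * cfg$stim_rate_gain
    spike_trains[[u]] <- synth_spikes(
      prof, dur, seed = derive_seed(seed, 10 + u), fs = fs,
      unit_id = sprintf("u%02d", u), channel = u, region = blk[u])
  }

  rec <- recording(lfp, fs, spike_trains, schedule, channel_meta,
                   list(group = group, condition = condition, duration = dur))
  list(recording = rec,
       ground_truth = list(coupling = cfg$coupling, block_labels = blk,
                           true_rates = cfg$base_rates))
}
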