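# Synthetic bistable-MEG data generation: stimulus timing, percept dynamics,
# source-level evoked responses with a planted state effect, and forward
# projection to sensors through a lead field.

#' Stimulus configuration for the A-B-A triplet paradigm
#'
#' Describes one continuous auditory streaming experiment: repeating A-B-A
#' tone triplets (A above B in frequency) presented in blocks, each triplet
#' plus the following silent gap defining one trial.
#'
#' @param tone_a_hz Frequency of the A tone (Hz).
#' @param tone_b_hz Frequency of the B tone (Hz).
#' @param tone_len_ms Duration of each tone (ms).
#' @param inter_tone_ms Gap between tones within the triplet (ms).
#' @param post_triplet_ms Silent gap after the triplet before the next one (ms).
#' @param trial_ms Total trial duration (ms); must equal
#'   `3 * tone_len_ms + 2 * inter_tone_ms + post_triplet_ms`.
#' @param block_s Block duration (s); `block_s * 1000 / trial_ms` must be an
#'   integer trial count.
#' @param n_blocks Number of blocks.
#' @param fs_hz Acquisition sampling rate (Hz); `trial_ms * fs_hz / 1000` must
#'   be an integer.
#' @param n_sensors Number of MEG channels (defaults to 274, a whole-head
#'   axial-gradiometer system with one channel excluded).
#'
#' @return An object of class `stimulus_config`.
#' @export
stimulus_config <- function(tone_a_hz = 1414, tone_b_hz = 1000,
                            tone_len_ms = 100, inter_tone_ms = 50,
                            post_triplet_ms = 200, trial_ms = 600,
                            block_s = 300, n_blocks = 6, fs_hz = 600,
                            n_sensors = 274) {
  if (3 * tone_len_ms + 2 * inter_tone_ms + post_triplet_ms != trial_ms)
    stop("trial_ms must equal 3*tone_len_ms + 2*inter_tone_ms + post_triplet_ms")
  trials_per_block <- block_s * 1000 / trial_ms
  if (abs(trials_per_block - round(trials_per_block)) > 1e-9)
    stop("block_s * 1000 / trial_ms must be an integer trial count")
  samples_per_trial <- trial_ms * fs_hz / 1000
  if (abs(samples_per_trial - round(samples_per_trial)) > 1e-9)
    stop("trial_ms * fs_hz / 1000 must be an integer number of samples")
  structure(list(
    tone_a_hz = tone_a_hz, tone_b_hz = tone_b_hz, tone_len_ms = tone_len_ms,
    inter_tone_ms = inter_tone_ms, post_triplet_ms = post_triplet_ms,
    trial_ms = trial_ms, block_s = block_s, n_blocks = n_blocks,
    fs_hz = fs_hz, n_sensors = n_sensors,
    trials_per_block = as.integer(round(trials_per_block)),
    samples_per_trial = as.integer(round(samples_per_trial))
  ), class = "stimulus_config")
}

#' Percept dominance-duration process
#'
#' Two-state renewal process with lognormally distributed dominance durations,
#' the canonical model for bistable-perception switch dynamics. States
#' strictly alternate; both states share the same duration distribution unless
#' the process is asymmetric by construction elsewhere.
#'
#' @param mu_log Mean of log duration (log-seconds).
#' @param sigma_log SD of log duration; must be >= 0.
#' @param state_labels Two state names, first is the initial state default.
#' @param initial_state Starting state.
#' @param seed Integer seed used by [generate_percept_sequence()].
#'
#' @return An object of class `percept_process`.
#' @export
percept_process <- function(mu_log = log(4), sigma_log = 0.7,
                            state_labels = c("gallop", "segregated"),
                            initial_state = state_labels[1], seed = 1L) {
  if (sigma_log < 0) stop("sigma_log must be >= 0")
  if (length(state_labels) != 2L)
    stop("exactly two state labels required")
  if (!initial_state %in% state_labels)
    stop("initial_state must be one of state_labels")
  structure(list(mu_log = mu_log, sigma_log = sigma_log,
                 state_labels = state_labels, initial_state = initial_state,
                 seed = as.integer(seed)),
            class = "percept_process")
}

#' Generate an alternating percept sequence
#'
#' Draws i.i.d. lognormal dominance durations and alternates states until the
#' requested span is covered; the final segment is truncated to fit exactly.
#'
#' @param process A [percept_process()].
#' @param total_s Total span to cover (s); must be > 0.
#' @param seed Optional override of `process$seed`.
#'
#' @return A data.frame with columns `state`, `duration_s`, `onset_s`.
#' @export
generate_percept_sequence <- function(process, total_s, seed = process$seed) {
  if (!is.numeric(total_s) || total_s <= 0) stop("total_s must be > 0")
  if (process$sigma_log < 0) stop("sigma_log must be >= 0")
  labs <- process$state_labels
  cur <- match(process$initial_state, labs)
  with_seed(seed, {
    states <- character(0); durs <- numeric(0)
    acc <- 0
    while (total_s - acc > 1e-9) {
      d <- stats::rlnorm(1, process$mu_log, process$sigma_log)
      states <- c(states, labs[cur]); durs <- c(durs, d)
      acc <- acc + d
      cur <- 3L - cur
    }
    durs[length(durs)] <- durs[length(durs)] - (acc - total_s)
    data.frame(state = states, duration_s = durs,
               onset_s = cumsum(c(0, durs[-length(durs)])))
  })
}

# Evaluate expr under a private seeded RNG stream, restoring the caller's
# .Random.seed afterwards so package simulations never perturb user state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Stimulus timeline: trial-onset sample indices
#'
#' Blocks are laid out as contiguous segments of the recording; within a block
#' trial onsets are spaced exactly one trial apart. Onsets are 0-based sample
#' indices (MEG event convention); sample 0 is the first sample.
#'
#' @param cfg A [stimulus_config()].
#' @return Integer vector of `n_blocks * trials_per_block` onset samples, with
#'   a `block` attribute giving each onset's block index.
#' @export
generate_stimulus_timeline <- function(cfg) {
  stopifnot(inherits(cfg, "stimulus_config"))
  block_samples <- cfg$block_s * cfg$fs_hz
  onsets <- unlist(lapply(seq_len(cfg$n_blocks) - 1L, function(b) {
    b * block_samples + (seq_len(cfg$trials_per_block) - 1L) * cfg$samples_per_trial
  }))
  structure(as.integer(onsets),
            block = rep(seq_len(cfg$n_blocks), each = cfg$trials_per_block))
}

#' State-dependent source effect description
#'
#' Defines the generative model of the evoked response: every trial evokes
#' `evoked_waveform` at the `evoked_sources`; trials falling in the second
#' percept state additionally receive `effect_amplitude` at the
#' `effect_sources` within `effect_window_ms` — the planted, recoverable
#' ground-truth difference between percepts.
#'
#' @param positions n_sources x 3 matrix of MNI coordinates (mm).
#' @param evoked_waveform Numeric vector, one trial's source time course
#'   sampled at the acquisition rate (length = samples per trial).
#' @param evoked_sources Indices of sources expressing the evoked response.
#' @param effect_sources Indices (subset of rows of `positions`) carrying the
#'   state difference.
#' @param effect_window_ms Two-element interval within the 0–600 ms trial.
#' @param effect_amplitude Additive amplitude difference between states
#'   (same units as `evoked_waveform`).
#' @param button_latency_mean_ms,button_latency_sd_ms Truncated-Gaussian
#'   motor-report lag applied to each perceptual switch (floor 0 ms).
#'
#' @return An object of class `source_effect`.
#' @export
source_effect <- function(positions, evoked_waveform,
                          evoked_sources = seq_len(nrow(positions)),
                          effect_sources = evoked_sources,
                          effect_window_ms = c(250, 267),
                          effect_amplitude = 1,
                          button_latency_mean_ms = 400,
                          button_latency_sd_ms = 100) {
  positions <- as.matrix(positions)
  if (ncol(positions) != 3L) stop("positions must be n x 3 (MNI mm)")
  if (any(effect_sources > nrow(positions)) || any(evoked_sources > nrow(positions)))
    stop("effect source index outside positions")
  if (effect_window_ms[1] < 0 || effect_window_ms[2] > 600 ||
      effect_window_ms[1] >= effect_window_ms[2])
    stop("effect_window_ms must lie within [0, 600] ms")
  structure(list(positions = positions, evoked_waveform = evoked_waveform,
                 evoked_sources = as.integer(evoked_sources),
                 effect_sources = as.integer(effect_sources),
                 effect_window_ms = effect_window_ms,
                 effect_amplitude = effect_amplitude,
                 button_latency_mean_ms = button_latency_mean_ms,
                 button_latency_sd_ms = button_latency_sd_ms),
            class = "source_effect")
}

#' Canonical auditory evoked waveform for one triplet trial
#'
#' A smooth stand-in for the auditory evoked field: one biphasic
#' (M50-like/M100-like) deflection per tone, each a difference of Gaussians
#' peaking ~50 and ~100 ms after tone onset. Used as the default
#' `evoked_waveform` of [source_effect()].
#'
#' @param cfg A [stimulus_config()].
#' @return Numeric vector of length `cfg$samples_per_trial`.
#' @export
triplet_evoked_waveform <- function(cfg) {
  t_ms <- (seq_len(cfg$samples_per_trial) - 1) / cfg$fs_hz * 1000
  tone_onsets <- (0:2) * (cfg$tone_len_ms + cfg$inter_tone_ms)
  w <- numeric(length(t_ms))
  for (on in tone_onsets) {
    w <- w + exp(-((t_ms - on - 50)^2) / (2 * 15^2)) -
      0.7 * exp(-((t_ms - on - 100)^2) / (2 * 25^2))
  }
  w
}

#' Default temporal-cortex source configuration
#'
#' Three sources — right auditory cortex (54, -14, 11), left auditory cortex
#' (-49, -20, 5) and a second right temporal source (50, -30, 8) — all
#' expressing the canonical triplet evoked waveform, with the state
#' difference planted at the two right-temporal sources inside the
#' 250–267 ms window.
#'
#' @param cfg A [stimulus_config()].
#' @param effect_amplitude Additive state difference; the default 0.3
#'   (relative to unit sensor noise) puts single-trial decoding in the weak
#'   regime typical of perceptual-state MEG decoding.
#' @param effect_window_ms State-difference window (ms).
#' @param ... Passed to [source_effect()].
#' @return A [source_effect()].
#' @export
default_effect <- function(cfg, effect_amplitude = 0.3,
                           effect_window_ms = c(250, 267), ...) {
  pos <- rbind(c(54, -14, 11), c(-49, -20, 5), c(50, -30, 8))
  source_effect(pos, triplet_evoked_waveform(cfg),
                evoked_sources = 1:3, effect_sources = c(1L, 3L),
                effect_amplitude = effect_amplitude,
                effect_window_ms = effect_window_ms, ...)
}

#' Simulate source time courses for a whole recording
#'
#' Deterministic given its inputs: each trial stamps the evoked waveform onto
#' the evoked sources; trials whose onset falls inside a segment of the second
#' percept state get the additive effect inside the effect window at the
#' effect sources.
#'
#' @param effect A [source_effect()].
#' @param timeline Onset samples from [generate_stimulus_timeline()].
#' @param percept_seq Ground-truth percept sequence
#'   (from [generate_percept_sequence()]).
#' @param cfg The [stimulus_config()].
#' @return n_sources x n_samples matrix; attribute `trial_state` records each
#'   trial's ground-truth percept.
#' @export
simulate_source_timecourses <- function(effect, timeline, percept_seq, cfg) {
  n_samples <- cfg$n_blocks * cfg$block_s * cfg$fs_hz
  n_src <- nrow(effect$positions)
  S <- matrix(0, n_src, n_samples)
  wf <- effect$evoked_waveform
  ns_trial <- length(wf)
  win <- round(effect$effect_window_ms / 1000 * cfg$fs_hz)
  win_idx <- (win[1] + 1):win[2]
  trial_state <- percept_state_at(percept_seq, timeline / cfg$fs_hz)
  # the additive state difference is carried by the "segregated" percept
  states <- unique(percept_seq$state)
  eff_state <- if ("segregated" %in% states) "segregated" else states[length(states)]
  for (i in seq_along(timeline)) {
    idx <- timeline[i] + seq_len(ns_trial)
    idx <- idx[idx <= n_samples]
    S[effect$evoked_sources, idx] <-
      S[effect$evoked_sources, idx, drop = FALSE] +
      matrix(wf[seq_along(idx)], length(effect$evoked_sources), length(idx),
             byrow = TRUE)
    if (!is.na(trial_state[i]) && trial_state[i] == eff_state) {
      wi <- win_idx[timeline[i] + win_idx <= n_samples]
      S[effect$effect_sources, timeline[i] + wi] <-
        S[effect$effect_sources, timeline[i] + wi, drop = FALSE] +
        effect$effect_amplitude
    }
  }
  attr(S, "trial_state") <- trial_state
  attr(S, "effect_state") <- eff_state
  S
}

# Percept state at given times (s); NA outside the covered span.
percept_state_at <- function(percept_seq, t_s) {
  ends <- percept_seq$onset_s + percept_seq$duration_s
  idx <- findInterval(t_s, percept_seq$onset_s)
  out <- rep(NA_character_, length(t_s))
  ok <- idx >= 1 & t_s < ends[pmax(idx, 1)]
  out[ok] <- percept_seq$state[idx[ok]]
  out
}

#' Random lead field with unit-norm columns
#'
#' Gaussian sensor topography per source, normalised to unit column norm — a
#' generic well-conditioned forward model standing in for a head-model-derived
#' lead field.
#'
#' @param n_sensors,n_sources Dimensions.
#' @param seed Integer seed.
#' @return n_sensors x n_sources matrix.
#' @export
synthetic_lead_field <- function(n_sensors, n_sources, seed = 1L) {
  L <- with_seed(seed,
    matrix(stats::rnorm(n_sensors * n_sources), n_sensors, n_sources))
  sweep(L, 2, sqrt(colSums(L^2)), "/")
}

#' Helmet-like sensor positions
#'
#' Deterministic Fibonacci-spiral coverage of the upper portion of a sphere
#' (radius 0.1 m), in head coordinates: +x right, +y anterior, +z superior.
#'
#' @param n_sensors Number of channels.
#' @return n_sensors x 3 matrix (m).
#' @export
sensor_positions <- function(n_sensors) {
  i <- seq_len(n_sensors)
  golden <- (1 + sqrt(5)) / 2
  # z spans the helmet cap, from just below the ears to the vertex
  z <- seq(-0.35, 0.99, length.out = n_sensors)
  r <- sqrt(pmax(0, 1 - z^2))
  th <- 2 * pi * i / golden
  0.1 * cbind(x = r * cos(th), y = r * sin(th), z = z)
}

#' Uniform random source grid in MNI space
#'
#' @param n_sources Number of sources.
#' @param seed Integer seed.
#' @return n_sources x 3 matrix of MNI coordinates (mm) inside a brain-sized
#'   bounding box.
#' @export
source_grid <- function(n_sources, seed = 1L) {
  with_seed(seed,
    cbind(x = stats::runif(n_sources, -70, 70),
          y = stats::runif(n_sources, -100, 70),
          z = stats::runif(n_sources, -45, 75)))
}

#' Project source activity to sensors and add noise
#'
#' @param lead_field sensors x sources matrix.
#' @param source_ts sources x samples matrix.
#' @param noise_sd SD of additive Gaussian sensor noise.
#' @param seed Integer seed for the noise.
#' @return sensors x samples matrix.
#' @export
forward_project <- function(lead_field, source_ts, noise_sd = 0, seed = 1L) {
  lead_field <- as.matrix(lead_field)
  if (nrow(source_ts) == 0) {
    data <- matrix(0, nrow(lead_field), ncol(source_ts))
  } else {
    if (ncol(lead_field) != nrow(source_ts))
      stop("lead_field columns must match source count")
    data <- lead_field %*% source_ts
  }
  if (noise_sd > 0) {
    data <- data + with_seed(seed,
      matrix(stats::rnorm(length(data), 0, noise_sd), nrow(data), ncol(data)))
  }
  data
}

# Button stream from the true percept sequence: every switch is delayed by a
# truncated-Gaussian motor latency; an optional "none" gap of switch_gap_ms is
# inserted after each (shifted) switch, and both_segments (list of c(start,end)
# in s) force the ambiguous "both buttons" state.
make_button_stream <- function(percept_seq, effect, fs_hz, n_samples, seed,
                               switch_gap_ms = 0, both_segments = NULL) {
  sw_t <- percept_seq$onset_s[-1]
  lat <- if (length(sw_t))
    with_seed(seed,
      pmax(0, stats::rnorm(length(sw_t), effect$button_latency_mean_ms,
                           effect$button_latency_sd_ms)) / 1000)
  else numeric(0)
  sw_shift <- sw_t + lat
  sw_shift <- cummax(sw_shift)         # latency never reorders switches
  bounds <- c(0, sw_shift, Inf)
  t_s <- (seq_len(n_samples) - 1) / fs_hz
  seg <- findInterval(t_s, bounds)
  stream <- percept_seq$state[pmin(seg, nrow(percept_seq))]
  if (switch_gap_ms > 0 && length(sw_shift)) {
    for (s in sw_shift) {
      gap <- t_s >= s & t_s < s + switch_gap_ms / 1000
      stream[gap] <- "none"
    }
  }
  if (!is.null(both_segments)) {
    for (bs in both_segments) stream[t_s >= bs[1] & t_s < bs[2]] <- "both"
  }
  stream
}

#' Generate a complete synthetic recording
#'
#' Runs the full generative chain — percept sequence, stimulus timeline,
#' source time courses with the planted state effect, forward projection with
#' sensor noise, and a latency-shifted button stream — and packages the result
#' with full provenance. Bit-reproducible for a given `(config, seed)`.
#'
#' @param cfg A [stimulus_config()].
#' @param process A [percept_process()].
#' @param effect A [source_effect()]; if `NULL`, a default 3-source
#'   temporal-cortex configuration with the canonical triplet waveform is used.
#' @param noise_sd Additive sensor noise SD (same units as the projected
#'   signal).
#' @param seed Master seed; all internal streams are derived from it.
#' @param lead_field Optional sensors x sources matrix; defaults to
#'   [synthetic_lead_field()].
#' @param switch_gap_ms "none"-state gap inserted at each reported switch (ms).
#' @param both_segments Optional list of `c(start_s, end_s)` intervals forced
#'   to the ambiguous "both" state.
#' @return A `meg_recording`: list with `data` (sensors x samples), `fs_hz`,
#'   `channel_pos`, `stim_onsets` (0-based), `button_stream`, `lead_field`,
#'   `source_pos`, `percept_seq` (ground truth) and `meta`.
#' @export
generate_dataset <- function(cfg = stimulus_config(),
                             process = percept_process(),
                             effect = NULL, noise_sd = 1, seed = 1L,
                             lead_field = NULL, switch_gap_ms = 0,
                             both_segments = NULL) {
  seed <- as.integer(seed)
  if (is.null(effect)) effect <- default_effect(cfg)
  total_s <- cfg$n_blocks * cfg$block_s
  n_samples <- total_s * cfg$fs_hz
  pseq <- generate_percept_sequence(process, total_s, seed = seed)
  timeline <- generate_stimulus_timeline(cfg)
  S <- simulate_source_timecourses(effect, timeline, pseq, cfg)
  if (is.null(lead_field))
    lead_field <- synthetic_lead_field(cfg$n_sensors, nrow(effect$positions),
                                       seed = seed + 1000L)
  data <- forward_project(lead_field, S, noise_sd, seed = seed + 2000L)
  stream <- make_button_stream(pseq, effect, cfg$fs_hz, n_samples,
                               seed = seed + 3000L,
                               switch_gap_ms = switch_gap_ms,
                               both_segments = both_segments)
  rec <- structure(list(
    data = data, fs_hz = cfg$fs_hz, channel_pos = sensor_positions(cfg$n_sensors),
    stim_onsets = timeline, button_stream = stream,
    lead_field = lead_field, source_pos = effect$positions,
    percept_seq = pseq,
    meta = list(cfg = cfg, process = process,
                effect = effect[setdiff(names(effect), "positions")],
                noise_sd = noise_sd, seed = seed,
                trial_state = attr(S, "trial_state"),
                schema_version = "1.0")
  ), class = "meg_recording")
  stopifnot(all(is.finite(rec$data)))
  rec
}
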