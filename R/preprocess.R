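# Preprocessing chain: zero-phase Butterworth filtering, downsampling,
# trial labelling from the button stream, switch-adjacent exclusion, epoching,
# baseline correction and robust (bisquare-weighted) averaging.

#' Filter and downsampling specification
#'
#' @param highpass_hz High-pass corner (Hz).
#' @param lowpass_hz Low-pass corner (Hz).
#' @param order Butterworth order for each filter (applied zero-phase, so the
#'   effective magnitude order doubles).
#' @param target_fs_hz Output sampling rate after decimation.
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(highpass_hz = 0.1, lowpass_hz = 30, order = 5,
                        target_fs_hz = 300) {
  if (!(highpass_hz > 0 && highpass_hz < lowpass_hz &&
        lowpass_hz < target_fs_hz / 2))
    stop("need 0 < highpass < lowpass < target_fs/2")
  structure(list(highpass_hz = highpass_hz, lowpass_hz = lowpass_hz,
                 order = order, target_fs_hz = target_fs_hz),
            class = "filter_spec")
}

# Zero-phase (forward-backward) filtering with odd-reflection padding so the
# long transient of a sub-Hz high-pass does not leak into the signal. Pad
# length covers ~3 time constants of the slowest corner, capped by the data.
ffilt <- function(flt, x, fs, slowest_hz) {
  n <- length(x)
  npad <- min(n - 1L, ceiling(3 / slowest_hz * fs))
  xp <- c(2 * x[1] - rev(x[2:(npad + 1)]), x,
          2 * x[n] - rev(x[(n - npad):(n - 1)]))
  y <- signal::filter(flt, xp)
  y <- rev(signal::filter(flt, rev(y)))
  y[(npad + 1):(npad + n)]
}

#' Band-pass filter and downsample a recording
#'
#' Applies the low-pass and high-pass Butterworth filters (separately, each
#' zero-phase) at the acquisition rate, then decimates to the target rate.
#' Event sample indices and the button stream are rescaled to the new rate.
#' Filtering is applied per block so block boundaries never leak into each
#' other.
#'
#' @param rec A `meg_recording`.
#' @param spec A [filter_spec()].
#' @return The recording, filtered, with `fs_hz = spec$target_fs_hz` and a
#'   `filtered` marker in `meta` (re-running is a no-op with a warning).
#' @export
filter_downsample <- function(rec, spec = filter_spec()) {
  stopifnot(inherits(rec, "meg_recording"))
  if (isTRUE(rec$meta$filtered)) {
    warning("recording already filtered; returning unchanged")
    return(rec)
  }
  fs <- rec$fs_hz
  if (fs < 2 * spec$lowpass_hz) stop("sampling rate below Nyquist for low-pass")
  factor <- fs / spec$target_fs_hz
  if (abs(factor - round(factor)) > 1e-9) {
    warning("fs not integer-divisible by target_fs; using polyphase resample")
  }
  bl <- signal::butter(spec$order, spec$lowpass_hz / (fs / 2), "low")
  bh <- signal::butter(spec$order, spec$highpass_hz / (fs / 2), "high")
  blocks <- block_bounds(rec)
  filt_one <- function(x) {
    out <- x
    for (b in seq_len(nrow(blocks))) {
      seg <- blocks[b, 1]:blocks[b, 2]
      y <- ffilt(bl, x[seg], fs, spec$lowpass_hz)
      out[seg] <- ffilt(bh, y, fs, spec$highpass_hz)
    }
    out
  }
  filtered <- t(apply(rec$data, 1, filt_one))
  if (abs(factor - round(factor)) <= 1e-9) {
    keep <- seq(1, ncol(filtered), by = round(factor))
    rec$data <- filtered[, keep, drop = FALSE]
    rec$button_stream <- rec$button_stream[keep]
  } else {
    rec$data <- t(apply(filtered, 1, function(x)
      signal::resample(x, spec$target_fs_hz, fs)))
    idx <- round(seq(1, ncol(filtered), length.out = ncol(rec$data)))
    rec$button_stream <- rec$button_stream[idx]
  }
  rec$stim_onsets <- structure(as.integer(floor(rec$stim_onsets / factor)),
                               block = attr(rec$stim_onsets, "block"))
  rec$fs_hz <- spec$target_fs_hz
  rec$meta$filtered <- TRUE
  rec$meta$filter_spec <- spec
  rec
}

# First/last sample index of each block (1-based); single block if no config.
block_bounds <- function(rec) {
  cfg <- rec$meta$cfg
  n <- ncol(rec$data)
  if (is.null(cfg)) return(cbind(1L, n))
  bs <- cfg$block_s * rec$fs_hz
  starts <- seq(1L, n, by = bs)
  cbind(starts, pmin(starts + bs - 1L, n))
}

#' Label trials from the button stream
#'
#' A trial is labelled with the single percept held throughout its window;
#' any mixture, a "none" or a "both" sample anywhere in the window makes it
#' `ambiguous`.
#'
#' @param rec A `meg_recording` (filtered or raw).
#' @param timeline Optional onset vector; defaults to `rec$stim_onsets`.
#' @return Character vector, one of `"gallop"`, `"segregated"`, `"ambiguous"`
#'   per trial.
#' @export
label_trials <- function(rec, timeline = rec$stim_onsets) {
  ns <- trial_samples(rec)
  n_total <- length(rec$button_stream)
  vapply(timeline, function(on) {
    idx <- (on + 1):(on + ns)
    idx <- idx[idx <= n_total]
    st <- unique(rec$button_stream[idx])
    if (length(st) == 1L && st %in% c("gallop", "segregated")) st
    else "ambiguous"
  }, character(1))
}

trial_samples <- function(rec) {
  trial_ms <- if (!is.null(rec$meta$cfg)) rec$meta$cfg$trial_ms else 600
  as.integer(round(trial_ms / 1000 * rec$fs_hz))
}

#' Drop switch-adjacent and ambiguous trials
#'
#' Perceptual switches are reported with motor latency, so the percept around
#' a reported switch is uncertain: for every label change between consecutive
#' unambiguous trials, the last `n_exclude` trials of the old state and the
#' first `n_exclude` of the new state are dropped. Ambiguous trials are always
#' dropped.
#'
#' @param labels Chronological trial labels from [label_trials()].
#' @param n_exclude Trials removed on each side of a switch.
#' @return Logical retention mask, same length as `labels`.
#' @export
exclude_switch_adjacent <- function(labels, n_exclude = 1L) {
  retained <- labels %in% c("gallop", "segregated")
  idx <- which(retained)
  if (length(idx) > 1L) {
    lab <- labels[idx]
    change <- which(lab[-1] != lab[-length(lab)])
    for (ci in change) {
      drop_old <- idx[seq(ci, max(1L, ci - n_exclude + 1L))]
      drop_new <- idx[seq(ci + 1L, min(length(idx), ci + n_exclude))]
      retained[c(drop_old, drop_new)] <- FALSE
    }
  }
  retained
}

#' Epoch a filtered recording
#'
#' Cuts fixed-length trials (0 to 600 ms from triplet onset by default) out of
#' the continuous data. Trials running past the end of the recording are
#' dropped from the retention mask with a message.
#'
#' @param rec A filtered `meg_recording`.
#' @param labels Trial labels from [label_trials()].
#' @param retained Retention mask from [exclude_switch_adjacent()]; defaults
#'   to all unambiguous.
#' @return An `epoch_set`: `data` (trials x sensors x samples; all trials),
#'   `fs_hz`, `window_ms`, `labels`, `retained`, `onsets`.
#' @export
epoch <- function(rec, labels, retained = labels != "ambiguous") {
  ns <- trial_samples(rec)
  n_total <- ncol(rec$data)
  onsets <- as.integer(rec$stim_onsets)
  fits <- onsets + ns <= n_total
  if (any(!fits & retained)) {
    message(sum(!fits & retained), " trial(s) extend past recording end; dropped")
  }
  retained <- retained & fits
  if (!any(retained)) stop("no retained epochs")
  n_trials <- length(onsets)
  arr <- array(NA_real_, c(n_trials, nrow(rec$data), ns))
  for (i in which(fits)) {
    arr[i, , ] <- rec$data[, (onsets[i] + 1):(onsets[i] + ns)]
  }
  structure(list(data = arr, fs_hz = rec$fs_hz,
                 window_ms = c(0, ns / rec$fs_hz * 1000),
                 labels = labels, retained = retained,
                 onsets = onsets, channel_pos = rec$channel_pos),
            class = "epoch_set")
}

#' Baseline-correct epochs
#'
#' Subtracts, per trial and channel, the mean over the baseline window. The
#' stimulus is continuous (no silent pre-stimulus period), so the default
#' baseline is the whole epoch.
#'
#' @param ep An `epoch_set`.
#' @param window_ms Baseline window `c(start, end)` in ms; `NULL` = whole epoch.
#' @return The corrected `epoch_set`.
#' @export
baseline_correct <- function(ep, window_ms = NULL) {
  ns <- dim(ep$data)[3]
  idx <- if (is.null(window_ms)) seq_len(ns) else {
    lo <- max(1L, floor(window_ms[1] / 1000 * ep$fs_hz) + 1L)
    hi <- min(ns, ceiling(window_ms[2] / 1000 * ep$fs_hz))
    lo:hi
  }
  bl <- apply(ep$data[, , idx, drop = FALSE], c(1, 2), mean)
  ep$data <- ep$data - array(rep(bl, ns), dim(ep$data))
  ep$meta_baseline <- if (is.null(window_ms)) "whole-epoch" else window_ms
  ep
}

#' Robust (bisquare-weighted) trial average
#'
#' Iteratively reweighted mean per channel and timepoint: residuals against
#' the current estimate are scaled by the across-trial MAD and weighted with
#' Tukey's bisquare, `w = (1 - (r / (k * MAD))^2)^2` for `|r| < k * MAD`, else
#' 0, so timepoints deviating from the bulk of trials are downweighted. If all
#' trials are rejected at a timepoint the estimate falls back to the median,
#' with a warning.
#'
#' @param ep A baseline-corrected `epoch_set`.
#' @param condition Label of the trials to average.
#' @param k Bisquare tuning constant (4.685 gives 95% Gaussian efficiency).
#' @param tol Convergence tolerance on the estimate.
#' @param max_iter Iteration cap.
#' @return List with `evoked` (sensors x samples) and `weights`
#'   (trials x sensors x samples).
#' @export
robust_average <- function(ep, condition, k = 4.685, tol = 1e-6,
                           max_iter = 20L) {
  sel <- which(ep$retained & ep$labels == condition)
  if (length(sel) < 2L) stop("need >= 2 retained trials in condition")
  d <- dim(ep$data)
  evoked <- matrix(NA_real_, d[2], d[3])
  weights <- array(NA_real_, c(length(sel), d[2], d[3]))
  fellback <- FALSE
  for (ch in seq_len(d[2])) {
    x <- ep$data[sel, ch, , drop = TRUE]            # trials x samples
    if (is.null(dim(x))) x <- matrix(x, nrow = length(sel))
    med <- apply(x, 2, stats::median)
    est <- med
    w <- matrix(1, nrow(x), ncol(x))
    for (it in seq_len(max_iter)) {
      r <- sweep(x, 2, est)
      madv <- apply(abs(sweep(r, 2, apply(r, 2, stats::median))), 2,
                    stats::median) * 1.4826
      thr <- k * madv
      u <- sweep(r, 2, ifelse(thr > 0, thr, Inf), "/")
      w <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
      zero_scale <- thr == 0
      if (any(zero_scale))
        w[, zero_scale] <- (r[, zero_scale, drop = FALSE] == 0) * 1
      sw <- colSums(w)
      dead <- sw == 0
      est_new <- ifelse(dead, med, colSums(w * x) / ifelse(dead, 1, sw))
      if (any(dead)) fellback <- TRUE
      if (max(abs(est_new - est)) < tol) { est <- est_new; break }
      est <- est_new
    }
    evoked[ch, ] <- est
    weights[, ch, ] <- w
  }
  if (fellback)
    warning("all-zero weights at some timepoint(s); median used there")
  list(evoked = evoked, weights = weights, trials = sel)
}

#' Robust-averaged evoked responses for both percepts
#'
#' @param ep A baseline-corrected `epoch_set`.
#' @param ... Passed to [robust_average()].
#' @return An `evoked_pair`: `evoked_gallop`, `evoked_segregated`
#'   (sensors x samples), `weights` (per condition), `fs_hz`, `channel_pos`.
#' @export
evoked_pair <- function(ep, ...) {
  g <- robust_average(ep, "gallop", ...)
  s <- robust_average(ep, "segregated", ...)
  structure(list(evoked_gallop = g$evoked, evoked_segregated = s$evoked,
                 weights = list(gallop = g$weights, segregated = s$weights),
                 fs_hz = ep$fs_hz, channel_pos = ep$channel_pos),
            class = "evoked_pair")
}

#' Run the full preprocessing chain
#'
#' filter -> downsample -> label -> switch-adjacent exclusion -> epoch ->
#' baseline correction, in the fixed order of the analysis pipeline.
#'
#' @param rec A raw `meg_recording`.
#' @param spec A [filter_spec()].
#' @param n_exclude Trials dropped on each side of a reported switch.
#' @param baseline_ms Baseline window, `NULL` for whole epoch.
#' @return A baseline-corrected `epoch_set`.
#' @export
preprocess_pipeline <- function(rec, spec = filter_spec(), n_exclude = 1L,
                                baseline_ms = NULL) {
  rec <- filter_downsample(rec, spec)
  labels <- label_trials(rec)
  retained <- exclude_switch_adjacent(labels, n_exclude)
  ep <- epoch(rec, labels, retained)
  baseline_correct(ep, baseline_ms)
}
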