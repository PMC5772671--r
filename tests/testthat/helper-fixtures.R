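# Shared scaled fixtures, built once per test run. Sizes are chosen so the
# whole chain (filter at 600 Hz, epoching, SVD, CVA/SVM, inversion) runs in
# seconds while keeping enough trials for the multivariate statistics.

scaled_cfg <- function(n_sensors = 30, block_s = 60, n_blocks = 2) {
  stimulus_config(block_s = block_s, n_blocks = n_blocks,
                  n_sensors = n_sensors)
}

.fx <- new.env()

# Noisy dataset + preprocessed epochs at the weak-effect default.
fixture_noisy <- function() {
  if (is.null(.fx$rec)) {
    cfg <- scaled_cfg()
    .fx$cfg <- cfg
    .fx$rec <- generate_dataset(cfg, percept_process(seed = 42),
                                effect = default_effect(cfg),
                                noise_sd = 1, seed = 42)
    .fx$ep <- preprocess_pipeline(.fx$rec)
    .fx$fm <- build_features(.fx$ep)
  }
  .fx
}

# Noiseless dataset with unit effect and exact (zero-latency) reports:
# every pipeline output is then a deterministic function of the planted
# ground truth.
fixture_noiseless <- function() {
  if (is.null(.fx$rec0)) {
    cfg <- scaled_cfg()
    eff <- default_effect(cfg, effect_amplitude = 1,
                          button_latency_mean_ms = 0,
                          button_latency_sd_ms = 0)
    .fx$eff0 <- eff
    .fx$rec0 <- generate_dataset(cfg, percept_process(seed = 7),
                                 effect = eff, noise_sd = 0, seed = 7)
    .fx$ep0 <- preprocess_pipeline(.fx$rec0)
  }
  .fx
}

# Minimal hand-built recording around a given data matrix (single block).
toy_recording <- function(data, fs = 600, onsets = integer(0),
                          stream = NULL) {
  if (is.null(stream)) stream <- rep("gallop", ncol(data))
  structure(list(data = data, fs_hz = fs,
                 channel_pos = sensor_positions(nrow(data)),
                 stim_onsets = as.integer(onsets), button_stream = stream,
                 lead_field = NULL, source_pos = NULL,
                 meta = list(cfg = NULL)),
            class = "meg_recording")
}

# Gaussian two-class feature set with a mean offset on every dimension.
toy_features <- function(n_per_class, p, delta = 0, seed = 1) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n_per_class * p), n_per_class),
             matrix(rnorm(n_per_class * p, mean = delta), n_per_class))
  list(X = X, y = factor(rep(c("gallop", "segregated"), each = n_per_class)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
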