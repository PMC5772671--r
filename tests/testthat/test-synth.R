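test_that("degenerate percept process yields exact alternating segments", {
  proc <- percept_process(mu_log = log(5), sigma_log = 0, seed = 1)
  seq <- generate_percept_sequence(proc, 20)
  expect_equal(nrow(seq), 4L)
  expect_equal(seq$duration_s, rep(5, 4))
  expect_equal(seq$state, rep(c("gallop", "segregated"), 2))
  expect_error(generate_percept_sequence(proc, -1), "total_s")
  expect_error(percept_process(sigma_log = -0.1), "sigma_log")
})

test_that("dominance durations match the lognormal closed-form mean", {
  proc <- percept_process(mu_log = log(8), sigma_log = 0.8)
  durs <- unlist(lapply(1:300, function(s) {
    d <- generate_percept_sequence(proc, 1800, seed = s)$duration_s
    d[-length(d)]   # last segment is truncated to fit the span
  }))
  mu_true <- exp(log(8) + 0.8^2 / 2)
  sd_true <- mu_true * sqrt(exp(0.8^2) - 1)
  se <- sd_true / sqrt(length(durs))
  expect_lt(abs(mean(durs) - mu_true), 3 * se)
})

test_that("both percepts occupy roughly half the time over long runs", {
  proc <- percept_process(mu_log = log(8), sigma_log = 0.8)
  total <- 10 * exp(log(8) + 0.8^2 / 2) * 100
  for (s in 1:3) {
    seq <- generate_percept_sequence(proc, total, seed = s)
    frac <- tapply(seq$duration_s, seq$state, sum) / total
    expect_true(all(frac > 0.4 & frac < 0.6))
  }
})

test_that("percept sequences are reproducible and strictly alternating", {
  proc <- percept_process(seed = 11)
  a <- generate_percept_sequence(proc, 300)
  b <- generate_percept_sequence(proc, 300)
  expect_identical(a, b)
  expect_true(all(a$state[-1] != a$state[-nrow(a)]))
  expect_equal(sum(a$duration_s), 300)
})

test_that("stimulus timeline has the full trial bookkeeping", {
  cfg <- stimulus_config()
  tl <- generate_stimulus_timeline(cfg)
  expect_length(tl, 3000L)
  expect_equal(unname(table(attr(tl, "block"))), rep(500L, 6), ignore_attr = TRUE)
  within_block <- diff(tl)[diff(attr(tl, "block")) == 0]
  expect_true(all(within_block == 360L))
  one <- generate_stimulus_timeline(stimulus_config(block_s = 0.6, n_blocks = 1))
  expect_equal(as.integer(one), 0L)
  expect_error(stimulus_config(block_s = 299), "integer trial count")
  expect_error(stimulus_config(fs_hz = 601), "integer number of samples")
})

test_that("source simulation plants exactly the configured state difference", {
  cfg <- stimulus_config(block_s = 6, n_blocks = 1, n_sensors = 4, fs_hz = 600)
  tl <- generate_stimulus_timeline(cfg)
  pos <- rbind(c(0, 0, 0), c(30, 0, 0))
  pseq <- data.frame(state = c("gallop", "segregated"),
                     duration_s = c(3, 3), onset_s = c(0, 3))

  # boxcar identity, single trial
  box <- rep(1, cfg$samples_per_trial)
  eff0 <- source_effect(pos, box, evoked_sources = 1L, effect_sources = 2L,
                        effect_amplitude = 0)
  cfg1 <- stimulus_config(block_s = 0.6, n_blocks = 1, n_sensors = 4)
  S1 <- simulate_source_timecourses(eff0, generate_stimulus_timeline(cfg1),
                                    data.frame(state = "gallop",
                                               duration_s = 0.6, onset_s = 0),
                                    cfg1)
  expect_equal(S1[1, ], box)
  expect_equal(S1[2, ], rep(0, length(box)))

  # zero amplitude: conditional averages identical
  S <- simulate_source_timecourses(eff0, tl, pseq, cfg)
  st <- attr(S, "trial_state")
  avg <- function(M, which) {
    idx <- which(st == which)
    Reduce(`+`, lapply(idx, function(i)
      M[, tl[i] + seq_len(cfg$samples_per_trial), drop = FALSE])) / length(idx)
  }
  expect_equal(avg(S, "gallop"), avg(S, "segregated"))

  # amplitude a: difference equals a inside 250-267 ms, 0 outside
  a <- 2.5
  eff <- source_effect(pos, box, evoked_sources = 1L, effect_sources = 2L,
                       effect_amplitude = a)
  S2 <- simulate_source_timecourses(eff, tl, pseq, cfg)
  d <- avg(S2, "segregated") - avg(S2, "gallop")
  win <- (round(0.250 * cfg$fs_hz) + 1):round(0.267 * cfg$fs_hz)
  expect_equal(unname(d[2, win]), rep(a, length(win)))
  expect_equal(unname(d[2, -win]), rep(0, cfg$samples_per_trial - length(win)))
  expect_equal(unname(d[1, ]), rep(0, cfg$samples_per_trial))

  expect_error(source_effect(pos, box, effect_sources = 5L), "index")
})

test_that("forward projection is the lead-field map plus seeded noise", {
  L <- synthetic_lead_field(8, 3, seed = 2)
  expect_equal(colSums(L^2), rep(1, 3))
  expect_equal(forward_project(L[, integer(0), drop = FALSE],
                               matrix(0, 0, 10)),
               matrix(0, 8, 10))
  s <- matrix(sin(1:50), 1)
  expect_equal(forward_project(L[, 1, drop = FALSE], s), L[, 1] %*% s)
  expect_error(forward_project(L, matrix(0, 2, 5)), "match")
  # law of large numbers on the noise scale
  noisy <- forward_project(matrix(0, 2, 1), matrix(0, 1, 1e5),
                           noise_sd = 1, seed = 3)
  expect_true(all(abs(apply(noisy, 1, sd) - 1) < 0.02))
})

test_that("generated datasets are deterministic and self-consistent", {
  cfg <- scaled_cfg(n_sensors = 8, block_s = 30, n_blocks = 1)
  r1 <- generate_dataset(cfg, percept_process(seed = 5), seed = 5)
  r2 <- generate_dataset(cfg, percept_process(seed = 5), seed = 5)
  expect_identical(r1, r2)
  expect_false(identical(
    r1$data, generate_dataset(cfg, percept_process(seed = 6), seed = 6)$data))

  # button stream conserves the recording length
  expect_length(r1$button_stream, ncol(r1$data))
  expect_true(all(r1$button_stream %in%
                    c("gallop", "segregated", "none", "both")))
  expect_false(any(r1$button_stream == "both"))

  # occupancy tracks the ground-truth percept up to motor-latency jitter
  occ <- table(r1$button_stream) / length(r1$button_stream)
  truth <- tapply(r1$percept_seq$duration_s, r1$percept_seq$state, sum) / 30
  for (st in names(truth))
    expect_lt(abs(occ[[st]] - truth[[st]]), 0.1)

  # ambiguity injection shows up, and only where requested
  r3 <- generate_dataset(cfg, percept_process(seed = 5), seed = 5,
                         both_segments = list(c(1, 2)))
  expect_true(any(r3$button_stream == "both"))
  tsec <- (seq_along(r3$button_stream) - 1) / r3$fs_hz
  expect_true(all(r3$button_stream[tsec < 1 | tsec >= 2] != "both"))
})

test_that("generated durations pass a lognormality check in >= 95% of runs", {
  proc <- percept_process(mu_log = log(4), sigma_log = 0.7)
  pass <- vapply(1:100, function(s) {
    d <- generate_percept_sequence(proc, 600, seed = s)$duration_s
    d <- d[-length(d)]
    lg <- log(d)
    suppressWarnings(
      stats::ks.test(lg, "pnorm", mean(lg), sd(lg))$p.value) > 0.01
  }, logical(1))
  expect_gte(mean(pass), 0.95)
})
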