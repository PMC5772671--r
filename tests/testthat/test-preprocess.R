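test_that("band-pass filtering removes DC and preserves the passband", {
  fs <- 600
  n <- fs * 60
  rec <- toy_recording(rbind(rep(1, n),                       # DC
                             sin(2 * pi * 10 * (1:n) / fs)),  # 10 Hz passband
                       fs = fs)
  out <- filter_downsample(rec, filter_spec())
  expect_equal(out$fs_hz, 300)
  expect_equal(ncol(out$data), 18000L)   # 60 s at 300 Hz
  mid <- 3000:15000
  expect_lt(max(abs(out$data[1, mid])), 0.01)           # DC gain ~ 0
  # Butterworth magnitude oracle per section at 10 Hz:
  # |H| = (1+(10/30)^10)^(-1/2) * (1+(0.1/10)^10)^(-1/2), squared (zero-phase)
  H <- (1 + (10 / 30)^10)^(-1) * (1 + (0.1 / 10)^(10))^(-1)
  amp <- max(abs(out$data[2, mid]))
  expect_lt(abs(amp - H) / H, 0.02)
  expect_warning(filter_downsample(out, filter_spec()), "already filtered")
})

test_that("trials are labelled by the single percept held over their window", {
  n <- 600 * 3
  stream <- rep("gallop", n)
  rec <- toy_recording(matrix(0, 2, n), onsets = c(0L, 600L, 1200L),
                       stream = stream)
  expect_equal(label_trials(rec), rep("gallop", 3))

  stream2 <- stream
  stream2[601:960] <- "both"
  rec2 <- toy_recording(matrix(0, 2, n), onsets = c(0L, 600L, 1200L),
                        stream = stream2)
  expect_equal(label_trials(rec2), c("gallop", "ambiguous", "gallop"))

  stream3 <- stream
  stream3[901:n] <- "segregated"   # switch mid second trial
  rec3 <- toy_recording(matrix(0, 2, n), onsets = c(0L, 600L, 1200L),
                        stream = stream3)
  expect_equal(label_trials(rec3), c("gallop", "ambiguous", "segregated"))
})

test_that("switch-adjacent exclusion drops one trial each side of a switch", {
  expect_equal(exclude_switch_adjacent(rep("gallop", 5)), rep(TRUE, 5))
  lab <- c("gallop", "gallop", "gallop", "segregated", "segregated",
           "segregated")
  expect_equal(exclude_switch_adjacent(lab),
               c(TRUE, TRUE, FALSE, FALSE, TRUE, TRUE))
  expect_equal(exclude_switch_adjacent(c("gallop", "segregated", "gallop")),
               rep(FALSE, 3))
  # ambiguous trials always dropped; switch over a gap still excludes
  lab2 <- c("gallop", "ambiguous", "segregated", "segregated")
  expect_equal(exclude_switch_adjacent(lab2), c(FALSE, FALSE, FALSE, TRUE))
  # wider exclusion
  lab3 <- c(rep("gallop", 4), rep("segregated", 4))
  expect_equal(exclude_switch_adjacent(lab3, n_exclude = 2),
               c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE))
})

test_that("epoching produces 180-sample trials and exact bookkeeping", {
  fx <- fixture_noisy()
  ep <- fx$ep
  expect_equal(dim(ep$data)[3], 180L)
  expect_equal(length(ep$labels), length(fx$rec$stim_onsets))
  expect_equal(sum(ep$retained) + sum(!ep$retained), length(ep$labels))
  expect_true(all(ep$labels[ep$retained] != "ambiguous"))

  # onset at sample 0 is an identity slice of the (filtered) continuous data
  n <- 300 * 4
  rec <- toy_recording(matrix(rnorm(2 * n), 2), fs = 300,
                       onsets = c(0L, 600L),
                       stream = rep("gallop", n))
  ep2 <- epoch(rec, label_trials(rec))
  expect_equal(ep2$data[1, , ], rec$data[, 1:180])

  # trials running past the end are dropped with a message
  rec3 <- toy_recording(matrix(0, 2, 400), fs = 300,
                        onsets = c(0L, 300L), stream = rep("gallop", 400))
  expect_message(ep3 <- epoch(rec3, label_trials(rec3)), "past recording end")
  expect_equal(ep3$retained, c(TRUE, FALSE))
  expect_error(epoch(rec3, rep("ambiguous", 2)), "no retained")
})

test_that("baseline correction zeroes the per-trial channel means", {
  fx <- fixture_noisy()
  ep <- fx$ep
  means <- apply(ep$data[which(ep$retained)[1:5], , , drop = FALSE],
                 c(1, 2), mean)
  expect_lt(max(abs(means)), 1e-10)
  # idempotent on already zero-mean data, removes a constant offset
  ep2 <- baseline_correct(ep)
  expect_equal(ep2$data, ep$data)
  ep3 <- ep
  ep3$data <- ep3$data + 7
  ep3 <- baseline_correct(ep3)
  expect_equal(ep3$data, ep$data)
})

test_that("robust averaging equals the mean on clean data and rejects outliers", {
  ns <- 40
  trial <- sin(2 * pi * (1:ns) / ns)
  make_ep <- function(trials) {
    structure(list(data = trials, fs_hz = 300, window_ms = c(0, 600),
                   labels = rep("gallop", dim(trials)[1]),
                   retained = rep(TRUE, dim(trials)[1])),
              class = "epoch_set")
  }
  clean <- array(rep(trial, each = 21), c(21, 1, ns))
  ra <- robust_average(make_ep(clean), "gallop")
  expect_equal(ra$evoked[1, ], trial)
  expect_true(all(ra$weights == 1))

  # one gross artifact at one timepoint
  set.seed(1)
  trials <- array(rep(trial, each = 21), c(21, 1, ns)) +
    array(rnorm(21 * ns, sd = 0.01), c(21, 1, ns))
  trials[21, 1, 10] <- trials[21, 1, 10] + 100 * max(abs(trial))
  ra2 <- robust_average(make_ep(trials), "gallop")
  expect_lt(ra2$weights[21, 1, 10], 0.01)
  clean_val <- mean(trials[1:20, 1, 10])
  expect_lt(abs(ra2$evoked[1, 10] - clean_val), 0.01 * max(abs(trial)))

  # convexity: the estimate stays within the trial range everywhere
  expect_true(all(ra2$evoked[1, ] >= apply(trials[, 1, ], 2, min) - 1e-12))
  expect_true(all(ra2$evoked[1, ] <= apply(trials[, 1, ], 2, max) + 1e-12))
})

test_that("noiseless pipeline reproduces the planted evoked difference", {
  fx <- fixture_noiseless()
  ep <- fx$ep0
  pair <- evoked_pair(ep)
  d <- pair$evoked_segregated - pair$evoked_gallop

  # oracle: preprocess the pure planted difference trace independently
  fs <- 600
  eff <- fx$eff0
  win <- (round(0.250 * fs) + 1):round(0.267 * fs)
  src_diff <- rep(0, fs * 60)
  src_diff[900 + win] <- eff$effect_amplitude   # one trial at sample 900
  L <- fx$rec0$lead_field
  sens <- (L[, 1] + L[, 3]) %o% src_diff
  bl <- signal::butter(5, 30 / 300, "low")
  bh <- signal::butter(5, 0.1 / 300, "high")
  filt <- t(apply(sens, 1, function(x)
    megstream:::ffilt(bh, megstream:::ffilt(bl, x, fs, 0.1), fs, 0.1)))
  keep <- seq(1, ncol(filt), 2)
  exp_ep <- filt[, keep][, (900 / 2 + 1):(900 / 2 + 180)]
  exp_ep <- exp_ep - rowMeans(exp_ep)
  expect_lt(max(abs(d - exp_ep)), 0.05 * eff$effect_amplitude)

  # and the planted amplitude survives inside the window at the best channel
  ch <- which.max(abs(L[, 1] + L[, 3]))
  win300 <- 76:80
  expect_gt(max(abs(d[ch, win300])),
            0.5 * abs(L[ch, 1] + L[ch, 3]) * eff$effect_amplitude)
})
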