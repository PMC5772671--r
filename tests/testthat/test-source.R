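make_epochs_from_sensor <- function(Y_list, channel_pos = NULL) {
  n <- length(Y_list)
  d <- dim(Y_list[[1]])
  arr <- array(NA_real_, c(n, d[1], d[2]))
  for (i in seq_len(n)) arr[i, , ] <- Y_list[[i]]
  structure(list(data = arr, fs_hz = 300, window_ms = c(0, 600),
                 labels = rep(c("gallop", "segregated"), length.out = n),
                 retained = rep(TRUE, n), channel_pos = channel_pos),
            class = "epoch_set")
}

test_that("a planted source is recovered as the posterior-variance argmax", {
  set.seed(1)
  n_sens <- 120; n_src <- 100
  L <- synthetic_lead_field(n_sens, n_src, seed = 1)
  pos <- source_grid(n_src, seed = 1)
  true_src <- 37L
  wave <- sin(2 * pi * (1:60) / 20)
  Y <- lapply(1:6, function(i) L[, true_src] %o% (wave * (0.8 + 0.1 * i)))
  ep <- make_epochs_from_sensor(Y)
  src <- min_norm_invert(ep, source_space(pos, L), lambda_reg = 1e-10,
                         n_temporal_modes = NULL)
  expect_equal(which.max(src$posterior_variance), true_src)
})

test_that("the inverse operator matches the ridge-regression oracle", {
  set.seed(2)
  L <- matrix(rnorm(20 * 40), 20)
  lam <- 0.5
  K <- t(solve(tcrossprod(L) + diag(lam, 20), L))
  y <- rnorm(20)
  # oracle: the normal-equations form (L'L + lam I)^-1 L' y
  j_oracle <- solve(crossprod(L) + diag(lam, 40), crossprod(L, y))
  expect_lt(max(abs(K %*% y - j_oracle)) / max(abs(j_oracle)), 1e-8)
})

test_that("inversion is linear and shrinks to zero with huge regularization", {
  set.seed(3)
  L <- synthetic_lead_field(15, 10, seed = 3)
  pos <- source_grid(10, seed = 3)
  Y1 <- lapply(1:4, function(i) matrix(rnorm(15 * 30), 15))
  Y2 <- lapply(1:4, function(i) matrix(rnorm(15 * 30), 15))
  Ys <- lapply(1:4, function(i) 2 * Y1[[i]] - 3 * Y2[[i]])
  inv <- function(Y) min_norm_invert(make_epochs_from_sensor(Y),
                                     source_space(pos, L), lambda_reg = 0.1,
                                     n_temporal_modes = NULL)$J
  expect_equal(inv(Ys), 2 * inv(Y1) - 3 * inv(Y2), tolerance = 1e-10)

  small <- min_norm_invert(make_epochs_from_sensor(Y1), source_space(pos, L),
                           lambda_reg = 1e-8, n_temporal_modes = NULL)$J
  tr <- sum(diag(tcrossprod(L)))
  big <- min_norm_invert(make_epochs_from_sensor(Y1), source_space(pos, L),
                         lambda_reg = 1e12 * tr, n_temporal_modes = NULL)$J
  expect_lt(max(abs(big)), 1e-6 * max(abs(small)))
})

test_that("temporal-mode reduction keeps the dominant dynamics", {
  set.seed(4)
  L <- synthetic_lead_field(12, 6, seed = 4)
  pos <- source_grid(6, seed = 4)
  wave <- sin(2 * pi * (1:90) / 30)
  Y <- lapply(1:8, function(i)
    L[, 2] %o% (wave * i / 4) + matrix(rnorm(12 * 90, sd = 1e-3), 12))
  src <- min_norm_invert(make_epochs_from_sensor(Y), source_space(pos, L),
                         lambda_reg = 1e-6, n_temporal_modes = 3)
  expect_equal(dim(src$J), c(8, 6, 90))
  expect_equal(which.max(src$posterior_variance), 2L)
  expect_equal(ncol(src$temporal_basis), 3L)
})

test_that("top-source selection enforces the separation rule", {
  pos <- rbind(c(0, 0, 0), c(8, 0, 0), c(40, 0, 0), c(80, 0, 0))
  v <- c(10, 9, 8, 7)
  expect_equal(select_top_sources(v, pos, k = 1), 1L)
  # second-best is 8 mm from the best -> skipped, distant ones promoted
  expect_equal(select_top_sources(v, pos, k = 3), c(1L, 3L, 4L))
  expect_warning(sel <- select_top_sources(c(5, 4), rbind(c(0, 0, 0), c(5, 0, 0)),
                                           k = 2),
                 "separation")
  expect_equal(sel, 1L)
})

test_that("greedy selection matches an independent best-first oracle", {
  oracle <- function(v, pos, k, min_dist) {
    chosen <- integer(0)
    cand <- order(v, decreasing = TRUE)
    while (length(chosen) < k && length(cand)) {
      i <- cand[1]; cand <- cand[-1]
      ok <- !length(chosen) ||
        all(sqrt(colSums((t(pos[chosen, , drop = FALSE]) - pos[i, ])^2)) >=
              min_dist)
      if (ok) chosen <- c(chosen, i)
    }
    chosen
  }
  set.seed(5)
  for (i in 1:20) {
    n <- sample(5:20, 1)
    pos <- source_grid(n, seed = i) / 2   # denser grid, more conflicts
    v <- runif(n)
    k <- sample(1:5, 1)
    expect_equal(
      suppressWarnings(select_top_sources(v, pos, k, min_dist_mm = 15)),
      suppressWarnings(oracle(v, pos, k, 15)))
  }
  # invariant: pairwise separation always holds
  pos <- source_grid(20, seed = 77) / 2
  sel <- suppressWarnings(select_top_sources(runif(20), pos, 5, 15))
  if (length(sel) > 1)
    expect_gte(min(dist(pos[sel, ])), 15)
})

test_that("ROI restriction picks the best in-sphere source", {
  set.seed(6)
  L <- synthetic_lead_field(15, 5, seed = 6)
  pos <- rbind(c(54, -14, 11), c(50, -10, 8), c(-49, -20, 5),
               c(34, -72, 38), c(0, 40, 20))
  Y <- lapply(1:6, function(i) L %*% matrix(rnorm(5 * 30, sd = c(3, 1, 1, 1, 1)), 5))
  src <- min_norm_invert(make_epochs_from_sensor(Y), source_space(pos, L),
                         lambda_reg = 1e-4, n_temporal_modes = NULL)
  rr <- roi_restrict(src, roi_spec("rAC", c(54, -14, 11), 10))
  inside <- which(rowSums(sweep(pos, 2, c(54, -14, 11))^2) <= 100)
  expect_true(rr$source_index %in% inside)
  expect_equal(src$posterior_variance[rr$source_index],
               max(src$posterior_variance[inside]))
  expect_error(roi_restrict(src, roi_spec("far", c(0, -200, 0), 5)),
               "far")
  # sphere centred exactly on a grid source, radius below spacing
  rr2 <- roi_restrict(src, roi_spec("exact", c(0, 40, 20), 3))
  expect_equal(rr2$source_index, 5L)
})

test_that("planted rAC effect is found in rAC and not in rPIPS", {
  cfg <- scaled_cfg(n_sensors = 24, block_s = 60, n_blocks = 1)
  pos <- rbind(c(54, -14, 11), c(-49, -20, 5), c(34, -72, 38))
  eff <- source_effect(pos, triplet_evoked_waveform(cfg),
                       evoked_sources = 1:3, effect_sources = 1L,
                       effect_amplitude = 1,
                       button_latency_mean_ms = 0, button_latency_sd_ms = 0)
  rec <- generate_dataset(cfg, percept_process(seed = 21), effect = eff,
                          noise_sd = 0.02, seed = 21)
  ep <- preprocess_pipeline(rec)
  src <- min_norm_invert(ep, source_space(pos, rec$lead_field))
  bal <- balance_source_trials(src)
  scr <- multi_roi_screen(bal, default_rois())
  expect_true(scr$significant[scr$name == "rAC"])
  expect_false(scr$significant[scr$name == "rPIPS"])
  # single-ROI consistency with the screen
  rr <- roi_restrict(bal, default_rois()$rAC)
  tf <- temporal_features(rr$tc, 5)
  r <- cva(tf$X, rr$y)
  expect_equal(r$p, scr$p[scr$name == "rAC"], tolerance = 1e-12)
})
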