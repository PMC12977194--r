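test_that("downsampling preserves in-band amplitude and suppresses aliases", {
  t2k <- seq(0, 2, by = 1 / 2000)
  rec40 <- recording(matrix(sin(2 * pi * 40 * t2k), nrow = 1), 2000, "a")
  out <- downsample_recording(rec40, 1000)
  expect_equal(ncol(out$samples), ceiling(length(t2k) / 2))
  expect_equal(out$fs, 1000)
  mid <- 500:1500
  expect_lt(abs(max(abs(out$samples[1, mid])) - 1), 0.01)   # within 1%

  rec900 <- recording(matrix(sin(2 * pi * 900 * t2k), nrow = 1), 2000, "a")
  out9 <- downsample_recording(rec900, 1000)
  expect_lt(max(abs(out9$samples[1, mid])), 0.05)           # anti-aliased

  expect_error(downsample_recording(rec40, 4000), "exceeds")
})

test_that("high-gamma envelope tracks passband tones and rejects stopband", {
  fs <- 1000
  tt <- seq(0, 5, by = 1 / fs)
  ss <- 1000:4000   # steady state away from edges
  env110 <- highgamma_envelope(sin(2 * pi * 110 * tt), fs)
  expect_lt(abs(mean(env110[ss]) - 1), 0.05)
  env30 <- highgamma_envelope(sin(2 * pi * 30 * tt), fs)
  expect_lt(mean(env30[ss]), 0.1)
  expect_equal(highgamma_envelope(numeric(5000), fs), numeric(5000))
  expect_error(highgamma_envelope(numeric(200), fs), "too short")
})

test_that("envelope is homogeneous of degree one in the input amplitude", {
  set.seed(3)
  x <- pink_noise(5000, 10)
  e1 <- highgamma_envelope(x, 1000)
  for (a in c(0.5, 2, 7)) {
    ea <- highgamma_envelope(a * x, 1000)
    expect_equal(ea, a * e1, tolerance = 1e-10)
  }
})

test_that("epoching does index arithmetic correctly and skips pressless trials", {
  fs <- 1000
  x <- numeric(8000)
  ev <- make_events()
  # impulse 100 ms after the first onset (sample index = onset*fs + 100 + 1)
  x[round(ev$onset_s[1] * fs) + 100 + 1] <- 1
  chan <- structure(list(raw = x, hg = x, env = abs(x), fs = fs,
                         site_id = "s"), class = "hg_channel")
  ep <- epoch(chan, ev, "stimulus", c(-500, 2000))
  expect_equal(nrow(ep$raw), 3)
  expect_equal(ncol(ep$raw), 2500)
  expect_equal(ep$raw[1, ep$times_ms == 100], 1)
  expect_true(all(ep$raw[1, ep$times_ms != 100] == 0))

  epp <- epoch(chan, ev, "press", c(-750, 500))
  expect_equal(nrow(epp$raw), 1)           # only one trial has a press
  expect_equal(epp$trial_index, 1L)

  ev_edge <- ev
  ev_edge$onset_s[1] <- 0.1                # epoch would start before t = 0
  expect_warning(ep2 <- epoch(chan, ev_edge, "stimulus", c(-500, 2000)),
                 "out of recording bounds")
  expect_equal(nrow(ep2$raw), 2)
})

test_that("ERBP is zero for constant envelopes and follows dB arithmetic", {
  times <- seq(-500, 1999)
  base <- times >= -200 & times < -50
  win <- times >= 50 & times < 300

  const <- make_epochs(matrix(3, nrow = 4, ncol = length(times)), times)
  erbp <- compute_erbp(const)
  expect_lt(max(abs(erbp$values)), 1e-9)

  env <- matrix(1, nrow = 2, ncol = length(times))
  env[, win] <- 2
  e2 <- compute_erbp(make_epochs(env, times))
  expect_equal(mean(e2$values[, win]), 20 * log10(2), tolerance = 1e-6)

  env[, win] <- sqrt(10)
  e10 <- compute_erbp(make_epochs(env, times))
  expect_equal(mean(e10$values[, win]), 10, tolerance = 1e-6)
})

test_that("per-trial baseline mean ERBP is identically zero", {
  set.seed(4)
  times <- seq(-500, 1999)
  base <- times >= -200 & times < -50
  env <- matrix(abs(rnorm(6 * length(times), 5, 2)), nrow = 6)
  erbp <- compute_erbp(make_epochs(env, times))
  expect_lt(max(abs(rowMeans(erbp$values[, base]))), 1e-10)
  # pooled mode zeroes the grand baseline mean instead
  pooled <- compute_erbp(make_epochs(env, times), baseline_mode = "pooled")
  expect_lt(abs(mean(pooled$values[, base])), 1e-10)
})

test_that("press-aligned ERBP requires an external baseline", {
  times <- seq(-750, 499)
  ep <- make_epochs(matrix(1, 2, length(times)), times, alignment = "press")
  expect_error(compute_erbp(ep), "press-aligned")
  ok <- compute_erbp(ep, baseline_db = c(0, -3))
  expect_equal(unique(ok$values[1, ]), 0 - 0, tolerance = 1e-9)
  expect_equal(unique(ok$values[2, ]), 0 + 3, tolerance = 1e-9)
})

test_that("artifact rejection applies the 5 SD raw and 10 SD band rules", {
  set.seed(5)
  n <- 500
  raw <- matrix(rnorm(5 * n), nrow = 5)
  raw <- raw * pmin(1, 4.5 / max(abs(raw)))        # keep clean trials < 5 SD
  ep <- make_epochs(raw, seq_len(n))
  st <- list(raw_mean = 0, raw_sd = 1, hg_mean = 0, hg_sd = 1)
  expect_true(all(reject_artifacts(ep, st)))

  ep$raw[2, 100] <- 6                               # raw spike at 6 SD
  keep <- reject_artifacts(ep, st)
  expect_equal(which(!keep), 2L)

  ep$raw[2, 100] <- 0
  ep$hg[4, 250] <- 11                               # band excursion at 11 SD
  keep <- reject_artifacts(ep, st)
  expect_equal(which(!keep), 4L)

  st0 <- list(raw_mean = 0, raw_sd = 0, hg_mean = 0, hg_sd = 1)
  expect_error(reject_artifacts(ep, st0), "degenerate")
})

test_that("injected burst amplitude ratios are recovered in window-mean ERBP", {
  # amplitude-modulated 110 Hz carrier whose envelope is r inside the
  # post-stimulus window and 1 elsewhere, plus 1/f noise 20 dB down
  fs <- 1000
  set.seed(6)
  n_tr <- 20
  onsets <- 2 + (0:(n_tr - 1)) * 2.8
  n <- round((max(onsets) + 2.6) * fs)
  tt <- (0:(n - 1)) / fs
  for (r in c(2, sqrt(10), 10)) {
    envp <- rep(1, n)
    for (o in onsets) {
      ramp_in <- tt >= o + 0.030 & tt < o + 0.050
      flat <- tt >= o + 0.050 & tt < o + 0.300
      ramp_out <- tt >= o + 0.300 & tt < o + 0.320
      envp[flat] <- r
      envp[ramp_in] <- 1 + (r - 1) * (tt[ramp_in] - o - 0.030) / 0.020
      envp[ramp_out] <- r - (r - 1) * (tt[ramp_out] - o - 0.300) / 0.020
    }
    x <- envp * cos(2 * pi * 110 * tt)
    noise <- pink_noise(n, 1, 1)
    b2 <- mean(highgamma_envelope(noise, fs)^2)
    x <- x + noise * sqrt(0.01 / b2)   # in-band noise floor at -20 dB
    ev <- data.frame(onset_s = onsets, duration_s = 0.3, label = "cat",
                     is_target = TRUE, press_s = onsets + 1,
                     rt_ms = 1000, outcome = "hit")
    chan <- prepare_channel(x, fs)
    ep <- epoch(chan, ev, "stimulus", c(-500, 2000))
    erbp <- compute_erbp(ep)
    meas <- mean(window_means(erbp, c(50, 300)))
    expect_lt(abs(meas - 20 * log10(r)), 0.5)
  }
})
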