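small_cfg <- function(seed = 1, ...) {
  simulation_config(rng_seed = seed,
                    site_plan = default_site_plan(sites_per_pattern = 1),
                    n_trials_per_block = 40, ...)
}

test_that("trial sequences follow the configured timing and determinism", {
  cfg <- simulation_config(rng_seed = 19)
  tr <- simulate_trials(cfg, "P01")
  # 140 onsets at ISI ~ N(2 s, 10 ms): span of onsets = 139 draws
  span <- diff(range(tr$events$onset_s))
  expect_lt(abs(span - 139 * 2), 1)
  isi <- diff(tr$events$onset_s)
  expect_lt(abs(mean(isi) - 2), 0.01)
  expect_lt(sd(isi), 0.02)
  expect_equal(sum(tr$events$is_target), 70)

  tr2 <- simulate_trials(cfg, "P01")
  expect_identical(tr, tr2)                       # same seed, same table
  tr3 <- simulate_trials(cfg, "P02")
  expect_false(identical(tr$events$onset_s, tr3$events$onset_s))
})

test_that("zero miss rate makes every target a hit", {
  cfg <- small_cfg(seed = 20, miss_rate = 0)
  tr <- simulate_trials(cfg, "P01")
  expect_true(all(tr$truth$outcome[tr$events$is_target] == "hit"))
})

test_that("generated reaction times match the configured lognormal median", {
  cfg <- simulation_config(rng_seed = 22, n_trials_per_block = 2100,
                           target_fraction = 0.5, miss_rate = 0,
                           site_plan = default_site_plan(sites_per_pattern = 1))
  tr <- simulate_trials(cfg, "P01")
  rts <- tr$truth$rt_ms[tr$truth$outcome == "hit"]
  expect_gte(length(rts), 1000)
  expect_lt(abs(median(rts) - 819) / 819, 0.05)
  expect_true(all(rts >= 400))
})

test_that("an empty site plan is rejected", {
  expect_error(simulation_config(site_plan = data.frame()), "nrow")
  plan <- default_site_plan(sites_per_pattern = 1)
  plan$roi[1] <- "XYZ"
  expect_error(simulation_config(site_plan = plan), "Unknown ROI")
})

test_that("burst calibration yields the intended window-mean ERBP", {
  cfg <- simulation_config(rng_seed = 23, amp_sigma_log = 0,
                           artifact_rate = 0,
                           site_plan = default_site_plan(sites_per_pattern = 1))
  sess <- simulate_session(cfg)
  for (k in which(sess$plan$intended_pattern %in% c("stimulus", "behavior"))) {
    p <- sess$plan$participant[k]
    sim <- simulate_site_signal(cfg, sess$plan[k, ], sess$trials[[p]],
                                b2 = sess$b2, site_key = k)
    ev <- score_trials(sess$trials[[p]]$events)
    res <- classify_channel(sim$x, cfg$fs_raw, ev, site_id = "s")
    if (sess$plan$intended_pattern[k] == "stimulus")
      expect_lt(abs(res$classification$mean_post_db - 6), 0.5)
    else
      expect_lt(abs(res$classification$mean_pre_db - 6), 0.5)
  }
})

test_that("perfect negative coupling yields rho = -1 on the true amplitudes", {
  plan <- default_site_plan(sites_per_pattern = 1)
  plan$rho_coupling[plan$intended_pattern == "stimulus"] <- -1
  cfg <- simulation_config(rng_seed = 24, site_plan = plan,
                           n_trials_per_block = 40)
  sess <- simulate_session(cfg)
  k <- which(plan$intended_pattern == "stimulus")
  p <- plan$participant[k]
  sim <- simulate_site_signal(cfg, plan[k, ], sess$trials[[p]],
                              b2 = sess$b2, site_key = k)
  hit <- sess$trials[[p]]$truth$outcome == "hit"
  expect_equal(site_spearman(sim$post_amp[hit],
                             sess$trials[[p]]$truth$rt_ms[hit]), -1)
})

test_that("artifact trials carry detectable pulses and get rejected", {
  cfg <- small_cfg(seed = 25, artifact_rate = 0.5)
  sess <- simulate_session(cfg)
  k <- which(sess$plan$intended_pattern == "none")
  p <- sess$plan$participant[k]
  sim <- simulate_site_signal(cfg, sess$plan[k, ], sess$trials[[p]],
                              b2 = sess$b2, site_key = k)
  expect_gt(sum(sim$artifact), 5)
  ev <- score_trials(sess$trials[[p]]$events)
  res <- classify_channel(sim$x, cfg$fs_raw, ev, site_id = "s")
  # retained trial count shrinks by roughly the artifact fraction
  n_candidates <- sum(ev$outcome == "hit" & ev$rt_ms > 550)
  expect_lt(res$classification$n_trials_used, n_candidates)
})

test_that("datasets on disk are reproducible and readable end to end", {
  cfg <- simulation_config(rng_seed = 26, n_participants = 2,
                           site_plan = default_site_plan(n_participants = 2,
                                                         sites_per_pattern = 1),
                           n_trials_per_block = 40)
  d1 <- file.path(withr::local_tempdir(), "a")
  d2 <- file.path(withr::local_tempdir(), "b")
  simulate_dataset(cfg, d1)
  simulate_dataset(cfg, d2)
  expect_identical(readLines(file.path(d1, "P01", "events.tsv")),
                   readLines(file.path(d2, "P01", "events.tsv")))
  expect_identical(readBin(file.path(d1, "P01", "recording.bin"), "raw", 4e5),
                   readBin(file.path(d2, "P01", "recording.bin"), "raw", 4e5))
  el <- read_electrodes_table(file.path(d1, "electrodes.tsv"))
  expect_equal(nrow(el), 4)
  rec <- read_recording(file.path(d1, "P01", "recording.bin"))
  expect_equal(rec$fs, cfg$fs_raw)
  gt <- jsonlite::read_json(file.path(d1, "ground_truth.json"),
                            simplifyVector = TRUE)
  expect_equal(sort(names(gt$sites)), sort(el$site_id))
})

test_that("ground-truth counts flow through the regional algebra unchanged", {
  # replacing the classifier with the true labels must reproduce the
  # intended per-ROI counts in prevalence and SB tables exactly
  cfg <- simulation_config(rng_seed = 27)
  sess <- simulate_session(cfg)
  cls <- data.frame(site_id = sess$plan$site_id,
                    pattern = sess$plan$intended_pattern)
  prev <- tabulate_prevalence(cls, sess$electrodes, "roi")
  stgp_l <- prev[prev$scope == "STGP" & prev$hemisphere == "L", ]
  n_expected <- sum(sess$plan$roi == "STGP" & sess$plan$hemisphere == "L")
  expect_equal(stgp_l$n_total, n_expected)
  expect_equal(stgp_l$n_stim, n_expected)
  expect_equal(stgp_l$prev_stim_pct, 100)

  sb <- sb_table(cls, sess$electrodes)
  mfg <- sb[sb$roi == "MFG" & sb$hemisphere == "L", ]
  expect_equal(mfg$n_behav, sum(sess$plan$roi == "MFG" &
                                  sess$plan$hemisphere == "L"))
  expect_equal(mfg$sb_index, 1)
})

test_that("label recovery at default SNR is accurate for active patterns", {
  study <- recovery_study()
  cm <- study$confusion
  diag_acc <- diag(cm) / rowSums(cm)
  # active labels are SNR-driven and must be recovered reliably
  expect_gte(diag_acc["stimulus"], 0.9)
  expect_gte(diag_acc["behavior"], 0.9)
  expect_gte(diag_acc["intermediate"], 0.9)
  # unresponsive sites are mislabelled at the nominal two-test alpha level:
  # expected correct fraction ~ (1 - alpha)^2 ~ 0.90
  expect_gte(diag_acc["none"], 0.85)
  expect_lte(diag_acc["none"], 0.95)
})
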