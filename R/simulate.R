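#' Simulation configuration
#'
#' Parameters of the synthetic target-detection session generator. Defaults
#' emulate the study conditions the analysis assumes: ~2 s Gaussian
#' inter-stimulus intervals (SD 10 ms), 300 ms stimuli, lognormal reaction
#' times with median 819 ms truncated below 400 ms, occasional misses and
#' false alarms, 1/f background noise at 2000 Hz, band-limited (70-150 Hz)
#' bursts with Gaussian amplitude envelopes (SD 60 ms) locked either to
#' stimulus onset (centre +150 ms) or to the button press (centre -125 ms),
#' and sporadic large-amplitude artifacts. One 140-trial block with half the
#' trials as targets yields roughly 60 retained hit trials per site.
#'
#' @param rng_seed Master seed; all per-participant and per-site streams are
#'   derived from it deterministically.
#' @param fs_raw Raw sampling rate (Hz).
#' @param n_participants Number of simulated participants.
#' @param site_plan Data.frame with one row per site: `participant`,
#'   `hemisphere`, `roi`, `intended_pattern`, `post_burst_db`,
#'   `pre_burst_db`, `rho_coupling`. See [default_site_plan()].
#' @param n_trials_per_block Trials per block.
#' @param isi_mean_s,isi_sd_s Gaussian inter-stimulus interval parameters (s).
#' @param stimulus_dur_s Stimulus duration (s).
#' @param target_fraction Fraction of trials that are targets.
#' @param rt_median_ms,rt_sigma_log Lognormal reaction-time model: median in
#'   ms and SD of log RT.
#' @param rt_min_ms,rt_max_ms Truncation bounds for reaction times (ms).
#' @param miss_rate Probability a target receives no press.
#' @param fa_rate Probability a nontarget receives a press.
#' @param noise_sd_uv Background noise SD in microvolts.
#' @param noise_exponent Spectral exponent of the 1/f background.
#' @param artifact_rate Per-trial probability of an injected artifact pulse.
#' @param artifact_sd_range Artifact magnitude range, in block SDs.
#' @param amp_sigma_log SD of log burst-amplitude multipliers across trials.
#' @param burst_sd_ms Gaussian burst envelope SD (ms).
#' @param post_burst_center_ms Stimulus-locked burst centre, ms after onset.
#' @param pre_burst_center_ms Press-locked burst centre, ms relative to press.
#' @param carrier_range_hz Range of per-trial burst carrier frequencies (Hz).
#' @return A list of class `hg_simconfig`.
#' @export
simulation_config <- function(rng_seed = 1L,
                              fs_raw = 2000,
                              n_participants = 3,
                              site_plan = default_site_plan(n_participants),
                              n_trials_per_block = 140,
                              isi_mean_s = 2, isi_sd_s = 0.010,
                              stimulus_dur_s = 0.3,
                              target_fraction = 0.5,
                              rt_median_ms = 819, rt_sigma_log = 0.25,
                              rt_min_ms = 400, rt_max_ms = 1900,
                              miss_rate = 0.08, fa_rate = 0.03,
                              noise_sd_uv = 10, noise_exponent = 1,
                              artifact_rate = 0.02,
                              artifact_sd_range = c(8, 12),
                              amp_sigma_log = 0.35,
                              burst_sd_ms = 60,
                              post_burst_center_ms = 150,
                              pre_burst_center_ms = -125,
                              carrier_range_hz = c(85, 135)) {
  stopifnot(nrow(site_plan) > 0,
            all(site_plan$post_burst_db >= 0),
            all(site_plan$pre_burst_db >= 0),
            all(abs(site_plan$rho_coupling) <= 1),
            target_fraction > 0, target_fraction < 1,
            miss_rate >= 0, miss_rate <= 1, fa_rate >= 0, fa_rate <= 1)
  roi_group_of(site_plan$roi)  # validates ROI labels
  if (!all(site_plan$participant %in%
           sprintf("P%02d", seq_len(n_participants))))
    stop("site_plan references unknown participants")
  cfg <- as.list(environment())
  class(cfg) <- "hg_simconfig"
  cfg
}

#' Default site plan
#'
#' Eighty sites, twenty per intended pattern, with each pattern concentrated
#' in one ROI so that regional analyses have well-powered cells:
#' stimulus-related sites in STGP (with a Spearman-level -0.3 coupling
#' between post-stimulus burst amplitude and reaction time), intermediate
#' sites in IFGop (uncoupled), behavior-related sites in MFG, and
#' unresponsive sites in MTGM. Sites alternate hemispheres and cycle through
#' the participants.
#'
#' @param n_participants Number of participants to cycle through.
#' @param sites_per_pattern Sites per intended pattern (default 20).
#' @param burst_db Window-mean ERBP of active components, dB (default 6).
#' @param rho_coupling Spearman-level coupling for the stimulus ROI.
#' @return Site-plan data.frame (see [simulation_config()]).
#' @export
default_site_plan <- function(n_participants = 3, sites_per_pattern = 20,
                              burst_db = 6, rho_coupling = -0.3) {
  spec <- list(
    list(pattern = "stimulus", roi = "STGP", post = burst_db, pre = 0,
         rho = rho_coupling),
    list(pattern = "intermediate", roi = "IFGop", post = burst_db,
         pre = burst_db, rho = 0),
    list(pattern = "behavior", roi = "MFG", post = 0, pre = burst_db,
         rho = 0),
    list(pattern = "none", roi = "MTGM", post = 0, pre = 0, rho = 0))
  rows <- list()
  k <- 0
  for (s in spec) for (i in seq_len(sites_per_pattern)) {
    k <- k + 1
    rows[[k]] <- data.frame(
      participant = sprintf("P%02d", ((k - 1) %% n_participants) + 1),
      hemisphere = c("L", "R")[(i %% 2) + 1],
      roi = s$roi, intended_pattern = s$pattern,
      post_burst_db = s$post, pre_burst_db = s$pre, rho_coupling = s$rho)
  }
  plan <- do.call(rbind, rows)
  plan$site_id <- sprintf("S%03d", seq_len(nrow(plan)))
  plan
}

.sub_seed <- function(seed, key) {
  as.integer((as.numeric(seed) * 7919 + key * 104729) %% 2147483629)
}

# Block length in samples: >= 3.5 s past the last onset, rounded up to a
# 2-3-5-composite length so the generator's FFT stays fast.
.block_samples <- function(cfg, events) {
  n0 <- round((events$onset_s[nrow(events)] + 3.5) * cfg$fs_raw)
  stats::nextn(n0, c(2, 3, 5))
}

#' 1/f background noise
#'
#' Gaussian-phase noise with amplitude spectrum proportional to
#' `f^(-exponent/2)`, scaled to the requested standard deviation.
#'
#' @param n Number of samples.
#' @param sd_uv Target SD in microvolts.
#' @param exponent Spectral exponent (1 = pink).
#' @return Numeric vector of length `n`.
#' @export
pink_noise <- function(n, sd_uv = 10, exponent = 1) {
  nf <- floor(n / 2)
  amp <- (1:nf)^(-exponent / 2)
  X <- complex(modulus = amp, argument = stats::runif(nf, 0, 2 * pi))
  full <- c(0, X, if (n %% 2 == 0) Conj(rev(X[-nf])) else Conj(rev(X)))
  x <- Re(stats::fft(full, inverse = TRUE))
  x * sd_uv / stats::sd(x)
}

# Noise envelope power through the analysis chain, estimated once per
# configuration on a reference realization. The reference has the same
# length as a simulated block: the 1/f background is normalized to a fixed
# time-domain SD, so its in-band power depends (logarithmically) on the
# record length and the reference must match it.
calibrate_noise_env <- function(cfg, acfg = analysis_config(),
                                ref_seconds = NULL) {
  set.seed(.sub_seed(cfg$rng_seed, 999983))
  if (is.null(ref_seconds))
    ref_seconds <- 2.5 + (cfg$n_trials_per_block - 1) * cfg$isi_mean_s + 3.5
  n <- stats::nextn(round(ref_seconds * cfg$fs_raw), c(2, 3, 5))
  x <- pink_noise(n, cfg$noise_sd_uv, cfg$noise_exponent)
  rec <- recording(matrix(x, nrow = 1), cfg$fs_raw, "ref")
  xd <- downsample_recording(rec, acfg$target_fs)$samples[1, ]
  env <- highgamma_envelope(xd, acfg$target_fs, acfg$hg_band_hz,
                            acfg$fir_order)
  mean(env[round(length(env) * 0.05):round(length(env) * 0.95)]^2)
}

# Expected ERBP (dB) of a burst of complex amplitude A*g(t) over noise with
# envelope power b2, using the exact mean of log Rician power:
# E[ln(Y/b2)] = ln(lambda) + E1(lambda) + gamma_E, lambda = (A g)^2 / b2.
.erbp_expected_db <- function(lambda) {
  gamma_e <- 0.577215664901533
  out <- numeric(length(lambda))
  pos <- lambda > 1e-12
  out[pos] <- (10 / log(10)) *
    (log(lambda[pos]) + pracma::expint_E1(lambda[pos]) + gamma_e)
  out
}

#' Burst peak amplitude for a target window-mean ERBP
#'
#' Inverts the expected log Rician power of a Gaussian-envelope burst over
#' 1/f background so that the mean ERBP across the analysis window equals
#' `target_db`.
#'
#' @param target_db Desired window-mean ERBP in dB.
#' @param b2 Noise envelope power through the analysis chain (microvolts^2).
#' @param window_ms Analysis window (ms relative to the alignment event).
#' @param center_ms Burst centre within the window's time base (ms).
#' @param sd_ms Burst envelope SD (ms).
#' @return Peak burst amplitude in microvolts.
#' @export
burst_amplitude <- function(target_db, b2, window_ms, center_ms, sd_ms = 60) {
  if (target_db <= 0) return(0)
  tt <- seq(window_ms[1], window_ms[2] - 1)
  g <- exp(-((tt - center_ms)^2) / (2 * sd_ms^2))
  pred <- function(loga) {
    A2 <- 10^(2 * loga)
    mean(.erbp_expected_db(A2 * g^2 / b2)) - target_db
  }
  a0 <- log10(sqrt(b2))
  10^stats::uniroot(pred, c(a0 - 4, a0 + 4), tol = 1e-8)$root
}

#' Simulate the trial sequence of one block
#'
#' Onsets accumulate Gaussian inter-stimulus intervals; target positions are
#' drawn at random; targets become hits (with a truncated-lognormal reaction
#' time) or misses; nontargets occasionally receive false-alarm presses.
#'
#' @param cfg An [simulation_config()].
#' @param participant Participant id (determines the random stream).
#' @return List with `events` (data.frame in the layout of
#'   [read_events_table()]) and `truth` (per-trial `outcome`, `rt_ms`,
#'   `z_rt` the standard-normal deviate behind each hit's reaction time).
#' @export
simulate_trials <- function(cfg, participant = "P01") {
  pid <- as.integer(sub("^P", "", participant))
  set.seed(.sub_seed(cfg$rng_seed, pid))
  n <- cfg$n_trials_per_block
  isi <- stats::rnorm(n - 1, cfg$isi_mean_s, cfg$isi_sd_s)
  onset <- 2.5 + c(0, cumsum(isi))
  n_target <- round(n * cfg$target_fraction)
  is_target <- rep(FALSE, n)
  is_target[sample.int(n, n_target)] <- TRUE
  label <- ifelse(is_target, sample(c("cat", "dog"), n, replace = TRUE),
                  sample(c("five", "ten", "red", "white"), n, replace = TRUE))
  draw_rt <- function() {
    repeat {
      z <- stats::rnorm(1)
      rt <- exp(log(cfg$rt_median_ms) + cfg$rt_sigma_log * z)
      if (rt >= cfg$rt_min_ms && rt <= cfg$rt_max_ms) return(c(rt, z))
    }
  }
  outcome <- character(n)
  rt_ms <- rep(NA_real_, n)
  z_rt <- rep(NA_real_, n)
  press_s <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (is_target[i]) {
      if (stats::runif(1) >= cfg$miss_rate) {
        d <- draw_rt()
        outcome[i] <- "hit"; rt_ms[i] <- d[1]; z_rt[i] <- d[2]
        press_s[i] <- onset[i] + d[1] / 1000
      } else outcome[i] <- "miss"
    } else {
      if (stats::runif(1) < cfg$fa_rate) {
        d <- draw_rt()
        outcome[i] <- "false_alarm"; rt_ms[i] <- d[1]
        press_s[i] <- onset[i] + d[1] / 1000
      } else outcome[i] <- "correct_reject"
    }
  }
  events <- data.frame(onset_s = onset, duration_s = cfg$stimulus_dur_s,
                       label = label, is_target = is_target,
                       press_s = press_s, rt_ms = rt_ms,
                       outcome = NA_character_, stringsAsFactors = FALSE)
  truth <- data.frame(trial = seq_len(n), outcome = outcome, rt_ms = rt_ms,
                      z_rt = z_rt, stringsAsFactors = FALSE)
  list(events = events, truth = truth)
}

#' Simulate one site's continuous channel
#'
#' 1/f background plus, for every hit trial, a band-limited tone burst with a
#' Gaussian amplitude envelope: a stimulus-locked component centred
#' `post_burst_center_ms` after onset and/or a press-locked component centred
#' `pre_burst_center_ms` relative to the button press, each scaled so that the
#' window-mean ERBP of the corresponding analysis window matches the site
#' plan's dB value. Per-trial amplitude multipliers are lognormal; for the
#' stimulus component they can be tied to reaction time through a Gaussian
#' copula at the requested Spearman level (`rho_coupling`). Artifacts are
#' injected as 10 ms square pulses of 8-12 block SDs at `artifact_rate` per
#' trial.
#'
#' @param cfg An [simulation_config()].
#' @param plan_row One row of the site plan.
#' @param trials Output of [simulate_trials()] for the site's participant.
#' @param b2 Noise envelope power from the calibration step (computed
#'   internally when `NULL`).
#' @param site_key Integer key for the site's random stream.
#' @param acfg Analysis configuration whose windows the calibration targets.
#' @return List with `x` (microvolt series at `fs_raw`), and per-trial truth:
#'   `post_amp`, `pre_amp` (burst peak amplitudes), `artifact` (logical).
#' @export
simulate_site_signal <- function(cfg, plan_row, trials, b2 = NULL,
                                 site_key = 1L, acfg = analysis_config()) {
  if (is.null(b2)) b2 <- calibrate_noise_env(cfg, acfg)
  set.seed(.sub_seed(cfg$rng_seed, 10000 + site_key))
  ev <- trials$events
  tr <- trials$truth
  n_tr <- nrow(ev)
  n <- .block_samples(cfg, ev)
  x <- pink_noise(n, cfg$noise_sd_uv, cfg$noise_exponent)
  noise_sd <- stats::sd(x)

  A_post <- burst_amplitude(plan_row$post_burst_db, b2, acfg$post_window_ms,
                            cfg$post_burst_center_ms, cfg$burst_sd_ms)
  A_pre <- burst_amplitude(plan_row$pre_burst_db, b2, acfg$pre_window_ms,
                           cfg$pre_burst_center_ms, cfg$burst_sd_ms)
  r_pearson <- 2 * sin(pi * plan_row$rho_coupling / 6)

  add_burst <- function(x, center_s, amp) {
    sd_s <- cfg$burst_sd_ms / 1000
    i0 <- max(1, round((center_s - 4 * sd_s) * cfg$fs_raw))
    i1 <- min(n, round((center_s + 4 * sd_s) * cfg$fs_raw))
    tt <- (i0:i1 - 1) / cfg$fs_raw
    g <- exp(-((tt - center_s)^2) / (2 * sd_s^2))
    fc <- stats::runif(1, cfg$carrier_range_hz[1], cfg$carrier_range_hz[2])
    ph <- stats::runif(1, 0, 2 * pi)
    x[i0:i1] <- x[i0:i1] + amp * g * cos(2 * pi * fc * tt + ph)
    x
  }

  hit <- which(tr$outcome == "hit")
  post_amp <- rep(NA_real_, n_tr)
  pre_amp <- rep(NA_real_, n_tr)
  for (i in hit) {
    if (A_post > 0) {
      z_amp <- r_pearson * tr$z_rt[i] +
        sqrt(max(0, 1 - r_pearson^2)) * stats::rnorm(1)
      m <- exp(cfg$amp_sigma_log * z_amp)
      post_amp[i] <- A_post * m
      x <- add_burst(x, ev$onset_s[i] + cfg$post_burst_center_ms / 1000,
                     post_amp[i])
    }
    if (A_pre > 0) {
      m <- exp(cfg$amp_sigma_log * stats::rnorm(1))
      pre_amp[i] <- A_pre * m
      x <- add_burst(x, ev$press_s[i] + cfg$pre_burst_center_ms / 1000,
                     pre_amp[i])
    }
  }

  artifact <- stats::runif(n_tr) < cfg$artifact_rate
  for (i in which(artifact)) {
    off_s <- stats::runif(1, -0.4, 1.8)
    i0 <- round((ev$onset_s[i] + off_s) * cfg$fs_raw)
    i1 <- min(n, i0 + round(0.010 * cfg$fs_raw))
    if (i0 < 1) next
    mag <- stats::runif(1, cfg$artifact_sd_range[1],
                        cfg$artifact_sd_range[2]) * noise_sd
    x[i0:i1] <- x[i0:i1] + sample(c(-1, 1), 1) * mag
  }

  list(x = x, post_amp = post_amp, pre_amp = pre_amp, artifact = artifact)
}

#' Simulate a full session in memory
#'
#' Builds trial tables for every participant, the electrode table from the
#' site plan (with plausible MNI coordinates), and the calibration constant;
#' site signals are generated on demand with [simulate_site_signal()].
#'
#' @param cfg An [simulation_config()].
#' @param acfg Analysis configuration used for calibration targets.
#' @return A list of class `hg_session`: `cfg`, `acfg`, `trials` (per
#'   participant), `electrodes`, `b2`.
#' @export
simulate_session <- function(cfg = simulation_config(),
                             acfg = analysis_config()) {
  participants <- sprintf("P%02d", seq_len(cfg$n_participants))
  trials <- lapply(participants, function(p) simulate_trials(cfg, p))
  names(trials) <- participants
  plan <- cfg$site_plan
  if (is.null(plan$site_id)) plan$site_id <- sprintf("S%03d", seq_len(nrow(plan)))
  set.seed(.sub_seed(cfg$rng_seed, 424243))
  roi_z <- c(STGP = 8, IFGop = 15, MFG = 30, MTGM = -15)
  zmu <- ifelse(plan$roi %in% names(roi_z), roi_z[plan$roi], 0)
  electrodes <- data.frame(
    site_id = plan$site_id,
    participant_id = plan$participant,
    hemisphere = plan$hemisphere,
    roi = plan$roi,
    roi_group = roi_group_of(plan$roi),
    x = ifelse(plan$hemisphere == "L", -1, 1) * stats::runif(nrow(plan), 35, 65),
    y = stats::rnorm(nrow(plan), -20, 15),
    z = stats::rnorm(nrow(plan), zmu, 8),
    stringsAsFactors = FALSE)
  structure(list(cfg = cfg, acfg = acfg, trials = trials,
                 electrodes = electrodes, plan = plan,
                 b2 = calibrate_noise_env(cfg, acfg)),
            class = "hg_session")
}

#' Write a synthetic dataset to disk
#'
#' Produces a directory readable by the package's readers with no further
#' arguments: one subdirectory per participant holding `recording.bin` (+
#' JSON sidecar) and `events.tsv`, plus `electrodes.tsv` and
#' `ground_truth.json` at the root.
#'
#' @param cfg An [simulation_config()].
#' @param out_dir Output directory (created if needed).
#' @param acfg Analysis configuration used for calibration targets.
#' @return `out_dir`, invisibly.
#' @export
simulate_dataset <- function(cfg = simulation_config(), out_dir,
                             acfg = analysis_config()) {
  sess <- simulate_session(cfg, acfg)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  truth <- list(sites = list(), trials = list())
  for (p in names(sess$trials)) {
    pdir <- file.path(out_dir, p)
    dir.create(pdir, showWarnings = FALSE)
    write_events_table(sess$trials[[p]]$events, file.path(pdir, "events.tsv"))
    truth$trials[[p]] <- sess$trials[[p]]$truth
    rows <- which(sess$plan$participant == p)
    sigs <- matrix(0, nrow = length(rows),
                   ncol = .block_samples(cfg, sess$trials[[p]]$events))
    for (j in seq_along(rows)) {
      k <- rows[j]
      sim <- simulate_site_signal(cfg, sess$plan[k, ], sess$trials[[p]],
                                  b2 = sess$b2, site_key = k, acfg = acfg)
      sigs[j, ] <- sim$x
      truth$sites[[sess$plan$site_id[k]]] <-
        list(intended_pattern = sess$plan$intended_pattern[k],
             post_burst_db = sess$plan$post_burst_db[k],
             pre_burst_db = sess$plan$pre_burst_db[k],
             rho_coupling = sess$plan$rho_coupling[k],
             artifact_trials = which(sim$artifact))
    }
    rec <- recording(sigs, cfg$fs_raw, sess$plan$site_id[rows],
                     block_id = paste0(p, "_block1"))
    write_recording(rec, file.path(pdir, "recording.bin"))
  }
  write_electrodes_table(sess$electrodes, file.path(out_dir, "electrodes.tsv"))
  jsonlite::write_json(truth, file.path(out_dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Run the label-recovery study on a synthetic session
#'
#' Generates every site of the session, runs the full single-site
#' classification chain, and returns recovered labels next to the intended
#' ones together with the per-site rho table for the RT-correlation
#' analysis.
#'
#' @param cfg An [simulation_config()].
#' @param acfg An [analysis_config()].
#' @return List: `classification` (with `intended_pattern` column),
#'   `rho_table`, `electrodes`, `session`.
#' @export
run_recovery <- function(cfg = simulation_config(),
                         acfg = analysis_config()) {
  sess <- simulate_session(cfg, acfg)
  results <- vector("list", nrow(sess$plan))
  for (k in seq_len(nrow(sess$plan))) {
    p <- sess$plan$participant[k]
    sim <- simulate_site_signal(cfg, sess$plan[k, ], sess$trials[[p]],
                                b2 = sess$b2, site_key = k, acfg = acfg)
    ev <- score_trials(sess$trials[[p]]$events)
    results[[k]] <- classify_channel(sim$x, cfg$fs_raw, ev, acfg,
                                     site_id = sess$plan$site_id[k])
  }
  names(results) <- sess$plan$site_id
  cls <- classification_table(results)
  cls$intended_pattern <- sess$plan$intended_pattern
  rho <- site_rho_table(results, sess$electrodes)
  list(classification = cls, rho_table = rho,
       electrodes = sess$electrodes, session = sess, results = results)
}
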