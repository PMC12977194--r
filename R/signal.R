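#' High-gamma FIR bandpass coefficients
#'
#' Window-method (Hamming) FIR design of the stated order for the 70-150 Hz
#' band (or any band below Nyquist).
#'
#' @param fs Sampling rate in Hz.
#' @param band Band edges in Hz, length 2.
#' @param order Filter order (number of taps minus one).
#' @return Numeric vector of `order + 1` filter coefficients.
#' @export
hg_fir <- function(fs, band = c(70, 150), order = 100) {
  if (band[2] >= fs / 2) stop("band edge at or above Nyquist")
  as.numeric(signal::fir1(order, band / (fs / 2), type = "pass"))
}

#' Apply an FIR filter with zero phase
#'
#' Forward-backward application, realised in the frequency domain: the signal
#' spectrum is multiplied by the squared magnitude response of the filter,
#' which is the transfer function of forward-backward time-domain filtering.
#' The signal is zero-padded past the next highly composite length plus one
#' filter length, so wrap-around affects only a filter length at each edge.
#'
#' @param x Numeric signal.
#' @param coef FIR coefficients.
#' @return Filtered signal, same length as `x`.
#' @export
fir_filtfilt <- function(x, coef) {
  n <- length(x)
  nt <- length(coef)
  if (n <= 3 * nt)
    stop("signal too short for zero-phase filtering (need > 3 filter lengths)")
  N <- stats::nextn(n + 2 * nt, c(2, 3, 5))
  H2 <- .fir_response2(coef, N)
  X <- stats::fft(c(x, rep(0, N - n)))
  y <- Re(stats::fft(X * H2, inverse = TRUE)) / N
  # |H|^2 is zero-phase: no group delay to remove
  y[seq_len(n)]
}

# memoized squared magnitude response of an FIR at FFT length N
.fir_cache <- new.env(parent = emptyenv())
.fir_response2 <- function(coef, N) {
  key <- paste0(N, "_", format(sum(coef * seq_along(coef)), digits = 17),
                "_", length(coef))
  if (!is.null(.fir_cache[[key]])) return(.fir_cache[[key]])
  H2 <- Mod(stats::fft(c(coef, rep(0, N - length(coef)))))^2
  .fir_cache[[key]] <- H2
  H2
}

#' Analytic-signal amplitude envelope
#'
#' Magnitude of the analytic signal (Hilbert transform method), computed by
#' zeroing negative frequencies in the discrete spectrum.
#'
#' @param x Numeric signal.
#' @return Envelope, same length as `x`.
#' @export
analytic_envelope <- function(x) {
  n <- length(x)
  N <- stats::nextn(n, c(2, 3, 5))
  X <- stats::fft(c(x, rep(0, N - n)))
  h <- rep(0, N)
  h[1] <- 1
  if (N %% 2 == 0) {
    h[N / 2 + 1] <- 1
    h[2:(N / 2)] <- 2
  } else {
    h[2:((N + 1) / 2)] <- 2
  }
  Mod(stats::fft(X * h, inverse = TRUE) / N)[seq_len(n)]
}

#' Downsample a recording with anti-aliasing
#'
#' Integer decimation factors use a zero-phase anti-alias FIR (order 100,
#' cutoff at 90% of the target Nyquist) followed by subsampling; non-integer
#' ratios fall back to polyphase resampling.
#'
#' @param rec An `hg_recording`.
#' @param target_fs Target sampling rate in Hz; must not exceed `rec$fs`.
#' @return An `hg_recording` at `target_fs`.
#' @export
downsample_recording <- function(rec, target_fs) {
  stopifnot(inherits(rec, "hg_recording"))
  if (target_fs > rec$fs) stop("target_fs exceeds recording sampling rate")
  if (target_fs == rec$fs) return(rec)
  q <- rec$fs / target_fs
  if (abs(q - round(q)) < 1e-9) {
    q <- round(q)
    lp <- as.numeric(signal::fir1(100, 0.9 / q))
    keep <- seq(1, ncol(rec$samples), by = q)
    out <- t(apply(rec$samples, 1, function(x) fir_filtfilt(x, lp)[keep]))
  } else {
    frac <- .rat(target_fs / rec$fs)
    out <- t(apply(rec$samples, 1,
                   function(x) signal::resample(x, frac$p, frac$q)))
  }
  recording(out, target_fs, rec$channel_ids, rec$block_id)
}

.rat <- function(r, tol = 1e-6) {
  for (q in 1:10000) {
    p <- r * q
    if (abs(p - round(p)) < tol) return(list(p = round(p), q = q))
  }
  stop("cannot express resampling ratio as a small rational")
}

#' High-gamma amplitude envelope of a single channel
#'
#' Zero-phase FIR bandpass (70-150 Hz by default, order 100) followed by
#' analytic-signal magnitude.
#'
#' @param x Numeric voltage series.
#' @param fs Sampling rate in Hz.
#' @param band Band edges in Hz.
#' @param order FIR order.
#' @return Envelope, same length as `x`.
#' @export
highgamma_envelope <- function(x, fs, band = c(70, 150), order = 100) {
  analytic_envelope(fir_filtfilt(x, hg_fir(fs, band, order)))
}

#' Precompute per-channel filtered signals
#'
#' Runs the band filtering and envelope extraction once on the continuous
#' signal so that both alignments can be epoched without repeating the
#' filtering.
#'
#' @param x Numeric voltage series at the analysis sampling rate.
#' @param fs Sampling rate in Hz.
#' @param cfg An [analysis_config()].
#' @param site_id Site identifier carried into downstream objects.
#' @return A list of class `hg_channel` with elements `raw`, `hg`, `env`,
#'   `fs`, `site_id`.
#' @export
prepare_channel <- function(x, fs, cfg = analysis_config(), site_id = "site") {
  hg <- fir_filtfilt(x, hg_fir(fs, cfg$hg_band_hz, cfg$fir_order))
  structure(list(raw = as.numeric(x), hg = hg, env = analytic_envelope(hg),
                 fs = fs, site_id = site_id),
            class = "hg_channel")
}

.window_cols <- function(window_ms, fs) {
  o1 <- round(window_ms[1] * fs / 1000)
  o2 <- round(window_ms[2] * fs / 1000)
  if (o2 <= o1) stop("empty analysis window")
  list(o1 = o1, o2 = o2, times_ms = (o1:(o2 - 1)) * 1000 / fs)
}

#' Extract event-aligned epochs
#'
#' Cuts trials x time epochs of the raw voltage, band-filtered voltage, and
#' amplitude envelope around each alignment event. For `alignment =
#' "stimulus"` every event contributes one row; for `"press"` only events
#' with a button press do. Windows are half-open `[start, end)` in ms
#' relative to the alignment event. Epochs that would extend beyond the
#' recording are dropped with a warning.
#'
#' @param chan An `hg_channel` from [prepare_channel()], or an
#'   `hg_recording` (its single channel, or `channel` must name one).
#' @param events Events data.frame (see [read_events_table()]).
#' @param alignment `"stimulus"` or `"press"`.
#' @param window_ms Epoch extent in ms, length 2.
#' @param cfg Analysis configuration (used only when `chan` is a recording).
#' @param channel Channel id to extract when `chan` is a multichannel
#'   recording.
#' @return A list of class `hg_epochs`: arrays `raw`, `hg`, `env`
#'   (trials x time), `times_ms`, `alignment`, `fs`, `trial_index` (row
#'   numbers into `events`), `site_id`.
#' @export
epoch <- function(chan, events, alignment = c("stimulus", "press"),
                  window_ms, cfg = analysis_config(), channel = NULL) {
  alignment <- match.arg(alignment)
  if (inherits(chan, "hg_recording")) {
    idx <- if (is.null(channel)) 1 else match(channel, chan$channel_ids)
    if (is.na(idx)) stop("unknown channel: ", channel)
    chan <- prepare_channel(chan$samples[idx, ], chan$fs, cfg,
                            site_id = chan$channel_ids[idx])
  }
  stopifnot(inherits(chan, "hg_channel"))
  fs <- chan$fs
  align_s <- if (alignment == "stimulus") events$onset_s else events$press_s
  trial_index <- which(!is.na(align_s))
  align_s <- align_s[trial_index]
  w <- .window_cols(window_ms, fs)
  centre <- round(align_s * fs) + 1L              # sample of the event
  start <- centre + w$o1
  stop_ <- centre + w$o2 - 1L
  ok <- start >= 1 & stop_ <= length(chan$raw)
  if (any(!ok)) {
    warning(sum(!ok), " epoch(s) out of recording bounds; dropped")
    trial_index <- trial_index[ok]
    start <- start[ok]
  }
  ncol_ <- w$o2 - w$o1
  slice <- function(sig) {
    out <- matrix(NA_real_, nrow = length(start), ncol = ncol_)
    for (i in seq_along(start))
      out[i, ] <- sig[start[i]:(start[i] + ncol_ - 1L)]
    out
  }
  structure(list(raw = slice(chan$raw), hg = slice(chan$hg),
                 env = slice(chan$env), times_ms = w$times_ms,
                 alignment = alignment, fs = fs, trial_index = trial_index,
                 site_id = chan$site_id),
            class = "hg_epochs")
}

#' Within-block voltage statistics for artifact screening
#'
#' @param chan An `hg_channel`.
#' @return List with `raw_mean`, `raw_sd`, `hg_mean`, `hg_sd` over the block.
#' @export
block_stats <- function(chan) {
  stopifnot(inherits(chan, "hg_channel"))
  list(raw_mean = mean(chan$raw), raw_sd = stats::sd(chan$raw),
       hg_mean = mean(chan$hg), hg_sd = stats::sd(chan$hg))
}

#' Artifact-based trial rejection
#'
#' A trial is rejected if any sample of its epoch deviates from the
#' within-block mean by more than `voltage_sd_thresh` block SDs in the raw
#' voltage, or by more than `hg_sd_thresh` block SDs in the band-filtered
#' voltage.
#'
#' @param epochs An `hg_epochs` object.
#' @param stats Block statistics from [block_stats()].
#' @param voltage_sd_thresh Raw-voltage threshold in SDs (default 5).
#' @param hg_sd_thresh Band-filtered threshold in SDs (default 10).
#' @return Logical keep-mask, one element per epoch row.
#' @export
reject_artifacts <- function(epochs, stats, voltage_sd_thresh = 5,
                             hg_sd_thresh = 10) {
  stopifnot(inherits(epochs, "hg_epochs"))
  if (stats$raw_sd <= 0 || stats$hg_sd <= 0)
    stop("degenerate recording: zero within-block SD")
  raw_ok <- apply(abs(epochs$raw - stats$raw_mean), 1, max) <=
    voltage_sd_thresh * stats$raw_sd
  hg_ok <- apply(abs(epochs$hg - stats$hg_mean), 1, max) <=
    hg_sd_thresh * stats$hg_sd
  raw_ok & hg_ok
}

#' Event-related band power
#'
#' Converts envelope epochs to log power in dB and normalises to a
#' prestimulus baseline: `ERBP(t) = 10*log10(env(t)^2 + eps) - B`, where `B`
#' is the mean of the same quantity over the baseline window. With
#' `baseline_mode = "per_trial"` (default) each trial uses its own baseline;
#' with `"pooled"` the baseline is the mean over all trials. `eps` is
#' `1e-12` times the maximum envelope power of the epochs, a floor that makes
#' the log well defined for identically zero input.
#'
#' For press-aligned matrices the baseline window does not lie inside the
#' epoch; supply `baseline_db` computed from the stimulus-aligned epochs of
#' the same trials.
#'
#' @param epochs An `hg_epochs` object (stimulus-aligned unless
#'   `baseline_db` is given).
#' @param baseline_window_ms Baseline window in ms relative to stimulus onset.
#' @param baseline_mode `"per_trial"` or `"pooled"`.
#' @param baseline_db Optional externally computed per-trial baseline (dB).
#' @return A list of class `hg_erbp`: `values` (trials x time, dB),
#'   `times_ms`, `alignment`, `trial_index`, `site_id`, `baseline_db`.
#' @export
compute_erbp <- function(epochs, baseline_window_ms = c(-200, -50),
                         baseline_mode = c("per_trial", "pooled"),
                         baseline_db = NULL) {
  stopifnot(inherits(epochs, "hg_epochs"))
  baseline_mode <- match.arg(baseline_mode)
  if (nrow(epochs$env) == 0) stop("no trials to compute ERBP from")
  eps <- 1e-12 * max(epochs$env^2, 1e-300)
  logp <- 10 * log10(epochs$env^2 + eps)
  if (is.null(baseline_db)) {
    if (epochs$alignment != "stimulus")
      stop("baseline must be computed from stimulus-aligned epochs; ",
           "pass baseline_db for press-aligned matrices")
    inb <- epochs$times_ms >= baseline_window_ms[1] &
      epochs$times_ms < baseline_window_ms[2]
    if (!any(inb)) stop("baseline window outside epoch extent")
    baseline_db <- rowMeans(logp[, inb, drop = FALSE])
    if (baseline_mode == "pooled")
      baseline_db <- rep(mean(baseline_db), length(baseline_db))
  } else if (length(baseline_db) != nrow(logp)) {
    stop("baseline_db length does not match trial count")
  }
  structure(list(values = logp - baseline_db, times_ms = epochs$times_ms,
                 alignment = epochs$alignment,
                 trial_index = epochs$trial_index, site_id = epochs$site_id,
                 baseline_db = baseline_db),
            class = "hg_erbp")
}

#' Subset trials of epoch or ERBP objects
#'
#' @param x An `hg_epochs` or `hg_erbp` object.
#' @param keep Logical or integer index over trials.
#' @return Object of the same class with the selected trials.
#' @export
subset_trials <- function(x, keep) {
  arr <- intersect(names(x), c("raw", "hg", "env", "values"))
  for (a in arr) x[[a]] <- x[[a]][keep, , drop = FALSE]
  x$trial_index <- x$trial_index[keep]
  if (!is.null(x$baseline_db) && length(x$baseline_db) > 1)
    x$baseline_db <- x$baseline_db[keep]
  x
}
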