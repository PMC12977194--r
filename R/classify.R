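#' Per-trial window means of an ERBP matrix
#'
#' Mean ERBP over a half-open `[start, end)` window for each retained trial.
#'
#' @param erbp An `hg_erbp` object.
#' @param window_ms Window in ms relative to the matrix alignment event.
#' @return Numeric vector, one mean per trial.
#' @export
window_means <- function(erbp, window_ms) {
  stopifnot(inherits(erbp, "hg_erbp"))
  if (nrow(erbp$values) == 0) stop("no trials in ERBP matrix")
  inw <- erbp$times_ms >= window_ms[1] & erbp$times_ms < window_ms[2]
  if (!any(inw)) stop("window outside the ERBP time axis")
  rowMeans(erbp$values[, inw, drop = FALSE])
}

#' One-tailed one-sample increase test
#'
#' Student t-test of H1: population mean > 0 against H0: mean <= 0, with
#' n - 1 degrees of freedom. Degenerate input (zero variance) yields p = 0
#' when the common value is positive and p = 1 otherwise, with a warning.
#'
#' @param values Per-trial window means.
#' @return One-tailed p-value.
#' @export
one_tailed_increase_test <- function(values) {
  if (length(values) < 2) stop("need at least 2 values")
  if (stats::sd(values) == 0) {
    warning("degenerate input: zero variance across trials")
    return(if (values[1] > 0) 0 else 1)
  }
  stats::t.test(values, alternative = "greater", mu = 0)$p.value
}

#' Classify a site from its two window p-values
#'
#' Significance is strict (`p < alpha`). Significant only post-stimulus:
#' `"stimulus"`; only pre-response: `"behavior"`; both: `"intermediate"`;
#' neither: `"none"`. Raw p-values are used by design: no site-level
#' multiple-comparison correction is applied, to minimise false negatives in
#' identifying responsive sites.
#'
#' @param p_post One-tailed p-value for the post-stimulus window.
#' @param p_pre One-tailed p-value for the pre-response window.
#' @param alpha Significance threshold (default 0.05).
#' @return One of `"stimulus"`, `"behavior"`, `"intermediate"`, `"none"`.
#' @export
classify_site <- function(p_post, p_pre, alpha = 0.05) {
  stopifnot(p_post >= 0, p_post <= 1, p_pre >= 0, p_pre <= 1)
  sig_post <- p_post < alpha
  sig_pre <- p_pre < alpha
  if (sig_post && sig_pre) "intermediate"
  else if (sig_post) "stimulus"
  else if (sig_pre) "behavior"
  else "none"
}

#' Full single-site classification chain
#'
#' Runs the complete per-site pipeline on one continuous channel: downsample
#' to the analysis rate, band filter and envelope, epoch in both alignments,
#' reject artifact trials jointly (a trial rejected in either alignment is
#' dropped from both so the same trials enter both window tests), compute
#' ERBP with a per-trial prestimulus baseline (press-aligned matrices reuse
#' the stimulus-aligned baselines), average the two analysis windows, and run
#' the one-tailed increase tests.
#'
#' Only hit trials with `rt_ms > min_rt_ms` enter the analysis.
#'
#' @param x Numeric voltage series (microvolts) at `fs`.
#' @param fs Sampling rate of `x` in Hz.
#' @param events Scored events data.frame for the same block.
#' @param cfg An [analysis_config()].
#' @param site_id Site identifier.
#' @param keep_erbp Keep the ERBP matrices in the result (memory-heavy).
#' @return A list of class `hg_site_result`: `classification` (one-row
#'   data.frame with `site_id`, `n_trials_used`, `mean_post_db`,
#'   `mean_pre_db`, `p_post`, `p_pre`, `pattern`), `post_means`, `pre_means`,
#'   `rt_ms` (per retained trial), and optionally `erbp_stim`, `erbp_press`.
#' @export
classify_channel <- function(x, fs, events, cfg = analysis_config(),
                             site_id = "site", keep_erbp = FALSE) {
  if (fs > cfg$target_fs) {
    rec <- recording(matrix(x, nrow = 1), fs, site_id)
    x <- downsample_recording(rec, cfg$target_fs)$samples[1, ]
    fs <- cfg$target_fs
  }
  chan <- prepare_channel(x, fs, cfg, site_id = site_id)
  hits <- filter_fast_hits(events, cfg$min_rt_ms)
  if (nrow(hits) < 2)
    stop("fewer than 2 retained hit trials for site ", site_id)
  st <- block_stats(chan)
  ep_stim <- epoch(chan, hits, "stimulus", cfg$stim_epoch_ms, cfg)
  ep_press <- epoch(chan, hits, "press", cfg$press_epoch_ms, cfg)
  common <- intersect(ep_stim$trial_index, ep_press$trial_index)
  ep_stim <- subset_trials(ep_stim, match(common, ep_stim$trial_index))
  ep_press <- subset_trials(ep_press, match(common, ep_press$trial_index))
  keep <- reject_artifacts(ep_stim, st, cfg$voltage_sd_thresh, cfg$hg_sd_thresh) &
    reject_artifacts(ep_press, st, cfg$voltage_sd_thresh, cfg$hg_sd_thresh)
  ep_stim <- subset_trials(ep_stim, keep)
  ep_press <- subset_trials(ep_press, keep)
  if (nrow(ep_stim$env) < 2)
    stop("fewer than 2 artifact-free trials for site ", site_id)
  erbp_stim <- compute_erbp(ep_stim, cfg$baseline_window_ms,
                            cfg$baseline_mode)
  erbp_press <- compute_erbp(ep_press, baseline_db = erbp_stim$baseline_db)
  post <- window_means(erbp_stim, cfg$post_window_ms)
  pre <- window_means(erbp_press, cfg$pre_window_ms)
  p_post <- one_tailed_increase_test(post)
  p_pre <- one_tailed_increase_test(pre)
  res <- list(classification = data.frame(
                site_id = site_id,
                n_trials_used = length(post),
                mean_post_db = mean(post), mean_pre_db = mean(pre),
                p_post = p_post, p_pre = p_pre,
                pattern = classify_site(p_post, p_pre, cfg$alpha_site),
                stringsAsFactors = FALSE),
              post_means = post, pre_means = pre,
              rt_ms = hits$rt_ms[match(ep_stim$trial_index,
                                       seq_len(nrow(hits)))])
  if (keep_erbp) {
    res$erbp_stim <- erbp_stim
    res$erbp_press <- erbp_press
  }
  class(res) <- "hg_site_result"
  res
}

#' Classify every channel of a recording
#'
#' @param rec An `hg_recording` (all channels are classified).
#' @param events Scored events for the same block.
#' @param cfg An [analysis_config()].
#' @param keep_erbp Keep per-site ERBP matrices.
#' @return A list of `hg_site_result`, named by site id.
#' @export
classify_recording <- function(rec, events, cfg = analysis_config(),
                               keep_erbp = FALSE) {
  stopifnot(inherits(rec, "hg_recording"))
  if (rec$fs > cfg$target_fs) rec <- downsample_recording(rec, cfg$target_fs)
  out <- lapply(seq_along(rec$channel_ids), function(i)
    classify_channel(rec$samples[i, ], rec$fs, events, cfg,
                     site_id = rec$channel_ids[i], keep_erbp = keep_erbp))
  names(out) <- rec$channel_ids
  out
}

#' Bind site classifications into one table
#'
#' @param results List of `hg_site_result` objects.
#' @return Data.frame with one row per site.
#' @export
classification_table <- function(results) {
  do.call(rbind, lapply(results, function(r) r$classification))
}
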