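#' Analysis configuration
#'
#' Bundles every tunable parameter of the pipeline. Defaults reproduce the
#' standard analysis: downsampling to 1000 Hz, a 70-150 Hz 100th-order FIR
#' bandpass applied zero-phase, per-trial baseline over 50-200 ms before
#' stimulus onset, 250 ms analysis windows (50-300 ms post-stimulus and
#' 250-0 ms pre-response), artifact rejection at 5 SD (raw voltage) and 10 SD
#' (band-filtered voltage) from the within-block mean, exclusion of hit trials
#' with reaction times not above 550 ms, and a site-level significance
#' threshold of 0.05 without multiple-comparison correction.
#'
#' All windows are in ms relative to the alignment event and are treated as
#' half-open intervals `[start, end)`. The 550 ms reaction-time floor
#' guarantees that the post-stimulus and pre-response windows never overlap
#' (550 >= 300 + 250).
#'
#' @param alpha_site Site-level significance threshold (strict `p < alpha`).
#' @param post_window_ms Post-stimulus analysis window, ms from stimulus onset.
#' @param pre_window_ms Pre-response analysis window, ms from button press.
#' @param baseline_window_ms Baseline window, ms from stimulus onset.
#' @param min_rt_ms Reaction-time floor; hits must have `rt_ms > min_rt_ms`.
#' @param hg_band_hz High-gamma band edges in Hz.
#' @param fir_order FIR filter order.
#' @param target_fs Analysis sampling rate in Hz.
#' @param voltage_sd_thresh Artifact threshold on raw voltage, in block SDs.
#' @param hg_sd_thresh Artifact threshold on band-filtered voltage, block SDs.
#' @param sb_min_sites Minimum stimulus+behavior sites for an SB index.
#' @param sb_min_participants Minimum participants spanned by those sites.
#' @param roi_min_sites_envelope Minimum qualifying sites for an ROI envelope.
#' @param roi_min_sites_rho Minimum sites for an ROI-level rho test.
#' @param stim_epoch_ms Stimulus-aligned epoch extent, ms.
#' @param press_epoch_ms Press-aligned epoch extent, ms.
#' @param envelope_window_ms Stimulus-aligned envelope display window, ms.
#' @param envelope_press_window_ms Press-aligned envelope display window, ms.
#' @param baseline_mode `"per_trial"` (default) or `"pooled"` (block-pooled
#'   baseline shared by all trials of a site).
#' @param fdr_family `"all"` (one family across all group-by-pattern tests)
#'   or `"per_pattern"` (one family per pattern).
#' @param rng_seed Integer seed for any stochastic step.
#' @return A list of class `hg_config`.
#' @export
analysis_config <- function(alpha_site = 0.05,
                            post_window_ms = c(50, 300),
                            pre_window_ms = c(-250, 0),
                            baseline_window_ms = c(-200, -50),
                            min_rt_ms = 550,
                            hg_band_hz = c(70, 150),
                            fir_order = 100,
                            target_fs = 1000,
                            voltage_sd_thresh = 5,
                            hg_sd_thresh = 10,
                            sb_min_sites = 5,
                            sb_min_participants = 2,
                            roi_min_sites_envelope = 10,
                            roi_min_sites_rho = 10,
                            stim_epoch_ms = c(-500, 2000),
                            press_epoch_ms = c(-750, 500),
                            envelope_window_ms = c(-100, 300),
                            envelope_press_window_ms = c(-400, 200),
                            baseline_mode = c("per_trial", "pooled"),
                            fdr_family = c("all", "per_pattern"),
                            rng_seed = 1L) {
  baseline_mode <- match.arg(baseline_mode)
  fdr_family <- match.arg(fdr_family)
  stopifnot(alpha_site > 0, alpha_site < 1,
            diff(post_window_ms) > 0, diff(pre_window_ms) > 0,
            diff(baseline_window_ms) > 0,
            target_fs > 0, fir_order > 0,
            hg_band_hz[1] > 0, hg_band_hz[2] > hg_band_hz[1],
            hg_band_hz[2] < target_fs / 2)
  if (min_rt_ms < post_window_ms[2] - pre_window_ms[1])
    stop("min_rt_ms must be at least ", post_window_ms[2] - pre_window_ms[1],
         " ms so the post-stimulus and pre-response windows cannot overlap")
  cfg <- list(alpha_site = alpha_site,
              post_window_ms = post_window_ms,
              pre_window_ms = pre_window_ms,
              baseline_window_ms = baseline_window_ms,
              min_rt_ms = min_rt_ms,
              hg_band_hz = hg_band_hz,
              fir_order = fir_order,
              target_fs = target_fs,
              voltage_sd_thresh = voltage_sd_thresh,
              hg_sd_thresh = hg_sd_thresh,
              sb_min_sites = sb_min_sites,
              sb_min_participants = sb_min_participants,
              roi_min_sites_envelope = roi_min_sites_envelope,
              roi_min_sites_rho = roi_min_sites_rho,
              stim_epoch_ms = stim_epoch_ms,
              press_epoch_ms = press_epoch_ms,
              envelope_window_ms = envelope_window_ms,
              envelope_press_window_ms = envelope_press_window_ms,
              baseline_mode = baseline_mode,
              fdr_family = fdr_family,
              rng_seed = as.integer(rng_seed))
  class(cfg) <- "hg_config"
  cfg
}

#' Read or write an analysis configuration as YAML
#'
#' @param path File path.
#' @return `read_config` returns an `hg_config`; `write_config` returns
#'   `path` invisibly.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(analysis_config))
  bad <- setdiff(names(raw), known)
  if (length(bad) > 0)
    stop("Unknown configuration field(s): ", paste(bad, collapse = ", "))
  do.call(analysis_config, raw)
}

#' @rdname read_config
#' @param cfg An `hg_config` object.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "hg_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
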