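#' Score trials into behavioral outcomes
#'
#' Attributes each button press to the most recent stimulus onset (a press is
#' valid for a stimulus if it occurs before the next onset) and labels each
#' trial: target with press = `hit`, target without press = `miss`, nontarget
#' with press = `false_alarm`, nontarget without press = `correct_reject`.
#' No minimum reaction time is applied here; fast hits are excluded later by
#' [filter_fast_hits()], not re-attributed.
#'
#' @param events Events data.frame sorted by onset (see
#'   [read_events_table()]).
#' @return The events data.frame with `outcome` filled and `rt_ms` set for
#'   trials with presses.
#' @export
score_trials <- function(events) {
  if (is.unsorted(events$onset_s))
    stop("events must be sorted by onset")
  events$outcome <- ifelse(events$is_target,
                           ifelse(!is.na(events$press_s), "hit", "miss"),
                           ifelse(!is.na(events$press_s), "false_alarm",
                                  "correct_reject"))
  events$rt_ms <- (events$press_s - events$onset_s) * 1000
  next_onset <- c(events$onset_s[-1], Inf)
  late <- !is.na(events$press_s) & events$press_s >= next_onset
  if (any(late))
    warning(sum(late), " press(es) fall after the next stimulus onset; ",
            "kept with their attributed trial")
  events
}

#' Behavioral sensitivity d'
#'
#' `d' = Z(hit rate) - Z(false-alarm rate)` with `Z` the standard-normal
#' quantile function. Rates of exactly 0 or 1 are clipped to
#' `[1/(2N), 1 - 1/(2N)]` (the standard log-linear correction) using the
#' relevant trial counts.
#'
#' @param hit_rate Hit rate as a proportion in \[0, 1\].
#' @param fa_rate False-alarm rate as a proportion in \[0, 1\].
#' @param n_targets Number of target trials (used only for clipping).
#' @param n_nontargets Number of nontarget trials (used only for clipping).
#' @return d' (numeric scalar).
#' @export
#' @examples
#' d_prime(0.9, 0.1)   # 2.5631
d_prime <- function(hit_rate, fa_rate, n_targets = 100, n_nontargets = 100) {
  stopifnot(hit_rate >= 0, hit_rate <= 1, fa_rate >= 0, fa_rate <= 1)
  clip <- function(p, n) pmin(pmax(p, 1 / (2 * n)), 1 - 1 / (2 * n))
  stats::qnorm(clip(hit_rate, n_targets)) -
    stats::qnorm(clip(fa_rate, n_nontargets))
}

#' Exclude fast hits
#'
#' Retains hit trials with `rt_ms > min_rt_ms` (strictly greater: a reaction
#' time of exactly 550 ms is excluded), guaranteeing that the post-stimulus
#' and pre-response analysis windows cannot overlap.
#'
#' @param events Scored events data.frame.
#' @param min_rt_ms Reaction-time floor in ms (default 550).
#' @return The hit trials that survive the filter.
#' @export
filter_fast_hits <- function(events, min_rt_ms = 550) {
  if (all(is.na(events$outcome))) stop("outcomes not assigned; run score_trials first")
  events[events$outcome == "hit" & !is.na(events$rt_ms) &
           events$rt_ms > min_rt_ms, , drop = FALSE]
}

#' Behavioral summary of a block
#'
#' Counts, rates (percent), sensitivity d' and median reaction time for one
#' set of scored trials.
#'
#' @param events Scored events data.frame.
#' @return One-row data.frame with `n_hits`, `n_misses`, `n_fas`, `n_crs`,
#'   `hit_rate` (%), `fa_rate` (%), `d_prime`, `median_rt_ms`.
#' @export
behavioral_summary <- function(events) {
  if (all(is.na(events$outcome))) stop("outcomes not assigned; run score_trials first")
  n_hits <- sum(events$outcome == "hit")
  n_misses <- sum(events$outcome == "miss")
  n_fas <- sum(events$outcome == "false_alarm")
  n_crs <- sum(events$outcome == "correct_reject")
  n_t <- n_hits + n_misses
  n_nt <- n_fas + n_crs
  hit_rate <- if (n_t > 0) n_hits / n_t else NA_real_
  fa_rate <- if (n_nt > 0) n_fas / n_nt else NA_real_
  data.frame(n_hits = n_hits, n_misses = n_misses, n_fas = n_fas,
             n_crs = n_crs,
             hit_rate = 100 * hit_rate, fa_rate = 100 * fa_rate,
             d_prime = if (!is.na(hit_rate) && !is.na(fa_rate))
               d_prime(hit_rate, fa_rate, n_t, n_nt) else NA_real_,
             median_rt_ms = stats::median(events$rt_ms[events$outcome == "hit"],
                                          na.rm = TRUE))
}
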