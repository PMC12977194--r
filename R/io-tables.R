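#' Read a trial/event table
#'
#' Tab-separated table with columns `onset`, `duration`, `label`, `is_target`
#' and `press_time` (seconds from block start; empty when no button press).
#' Events are returned sorted by onset with `rt_ms` computed where a press is
#' present; the `outcome` column is left `NA` and is assigned by
#' [score_trials()].
#'
#' @param path Path to the events TSV.
#' @return A data.frame with columns `onset_s`, `duration_s`, `label`,
#'   `is_target`, `press_s`, `rt_ms`, `outcome`.
#' @export
read_events_table <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          na.strings = c("", "n/a", "NA"))
  need <- c("onset", "duration", "label", "is_target", "press_time")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("format error: events table missing column(s): ",
         paste(miss, collapse = ", "))
  if (is.unsorted(df$onset, strictly = TRUE))
    stop("format error: event onsets must be strictly increasing")
  press <- as.numeric(df$press_time)
  if (any(!is.na(press) & press <= df$onset))
    stop("format error: press_time at or before stimulus onset")
  data.frame(onset_s = as.numeric(df$onset),
             duration_s = as.numeric(df$duration),
             label = as.character(df$label),
             is_target = as.logical(df$is_target),
             press_s = press,
             rt_ms = (press - as.numeric(df$onset)) * 1000,
             outcome = NA_character_,
             stringsAsFactors = FALSE)
}

#' Write a trial/event table
#'
#' Inverse of [read_events_table()]; `rt_ms` and `outcome` are derived
#' columns and are not written.
#'
#' @param events Events data.frame.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_events_table <- function(events, path) {
  out <- data.frame(onset = events$onset_s,
                    duration = events$duration_s,
                    label = events$label,
                    is_target = events$is_target,
                    press_time = ifelse(is.na(events$press_s), "n/a",
                                        format(events$press_s, digits = 15)))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "n/a")
  invisible(path)
}

#' Read an electrode/site table
#'
#' Tab-separated table with columns `site`, `participant`, `hemisphere`,
#' `roi`, `x`, `y`, `z` (MNI coordinates in mm). The ROI group is filled from
#' the built-in parcellation ([roi_table()]); unknown ROI labels are an
#' error. Right-hemisphere x coordinates are stored as-is (mirroring is a
#' plotting concern only).
#'
#' @param path Path to the electrodes TSV.
#' @return A data.frame with columns `site_id`, `participant_id`,
#'   `hemisphere`, `roi`, `roi_group`, `x`, `y`, `z`.
#' @export
read_electrodes_table <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("site", "participant", "hemisphere", "roi", "x", "y", "z")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("format error: electrodes table missing column(s): ",
         paste(miss, collapse = ", "))
  if (!all(df$hemisphere %in% c("L", "R")))
    stop("validation error: hemisphere must be 'L' or 'R'")
  if (anyDuplicated(df$site))
    stop("validation error: duplicate site ids")
  data.frame(site_id = as.character(df$site),
             participant_id = as.character(df$participant),
             hemisphere = df$hemisphere,
             roi = df$roi,
             roi_group = roi_group_of(df$roi),
             x = as.numeric(df$x), y = as.numeric(df$y), z = as.numeric(df$z),
             stringsAsFactors = FALSE)
}

#' @rdname read_electrodes_table
#' @param electrodes Electrodes data.frame (as returned by
#'   `read_electrodes_table`).
#' @export
write_electrodes_table <- function(electrodes, path) {
  out <- data.frame(site = electrodes$site_id,
                    participant = electrodes$participant_id,
                    hemisphere = electrodes$hemisphere,
                    roi = electrodes$roi,
                    x = electrodes$x, y = electrodes$y, z = electrodes$z)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
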