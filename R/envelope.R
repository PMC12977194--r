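#' Grand-average ERBP envelope for one ROI
#'
#' Each site's ERBP matrix is first averaged across its retained trials, then
#' the site-level envelopes are averaged across sites; the across-site 95%
#' confidence band is a pointwise t-interval. The averaging order
#' (trials-then-sites) weights every site equally regardless of trial count.
#'
#' @param erbp_list List of `hg_erbp` matrices, one per qualifying site, all
#'   sharing alignment and time axis.
#' @param window_ms Display window in ms (default -100 to 300 for
#'   stimulus-aligned envelopes).
#' @param min_sites Minimum number of sites (default 10); fewer is an error
#'   so that callers can omit the ROI.
#' @param conf_level Confidence level for the band (default 0.95).
#' @return A list of class `hg_roi_envelope`: `times_ms`, `mean_db`,
#'   `ci_low`, `ci_high`, `n_sites`, `alignment`.
#' @export
grand_average_envelope <- function(erbp_list, window_ms = c(-100, 300),
                                   min_sites = 10, conf_level = 0.95) {
  n_sites <- length(erbp_list)
  if (n_sites < min_sites)
    stop("ROI has ", n_sites, " site(s); at least ", min_sites, " required")
  al <- unique(vapply(erbp_list, function(e) e$alignment, ""))
  if (length(al) != 1) stop("mixed alignments in envelope averaging")
  times <- erbp_list[[1]]$times_ms
  inw <- times >= window_ms[1] & times < window_ms[2]
  if (!any(inw)) stop("display window outside the ERBP time axis")
  site_mean <- t(vapply(erbp_list,
                        function(e) colMeans(e$values[, inw, drop = FALSE]),
                        numeric(sum(inw))))
  m <- colMeans(site_mean)
  se <- apply(site_mean, 2, stats::sd) / sqrt(n_sites)
  tcrit <- stats::qt(1 - (1 - conf_level) / 2, df = n_sites - 1)
  structure(list(times_ms = times[inw], mean_db = m,
                 ci_low = m - tcrit * se, ci_high = m + tcrit * se,
                 n_sites = n_sites, alignment = al),
            class = "hg_roi_envelope")
}

#' ROI envelope table across qualifying ROIs
#'
#' Builds long-format grand-average envelopes for every ROI with at least
#' `min_sites` sites whose pattern qualifies for the given alignment
#' (stimulus-aligned: stimulus-related or intermediate sites; press-aligned:
#' behavior-related or intermediate sites).
#'
#' @param results List of `hg_site_result` objects holding ERBP matrices
#'   (run [classify_channel()] with `keep_erbp = TRUE`).
#' @param site_meta Electrode metadata.
#' @param alignment `"stimulus"` or `"press"`.
#' @param window_ms Display window; defaults to -100..300 ms for stimulus
#'   alignment and -400..200 ms for press alignment.
#' @param min_sites Minimum qualifying sites per ROI (default 10).
#' @return Long data.frame: `roi`, `alignment`, `time_ms`, `mean_db`, `lo`,
#'   `hi`, `n_sites`.
#' @export
roi_envelopes <- function(results, site_meta,
                          alignment = c("stimulus", "press"),
                          window_ms = NULL, min_sites = 10) {
  alignment <- match.arg(alignment)
  if (is.null(window_ms))
    window_ms <- if (alignment == "stimulus") c(-100, 300) else c(-400, 200)
  want <- if (alignment == "stimulus") c("stimulus", "intermediate")
          else c("behavior", "intermediate")
  slot <- if (alignment == "stimulus") "erbp_stim" else "erbp_press"
  rows <- list()
  pats <- vapply(results, function(r) r$classification$pattern, "")
  rois <- site_meta$roi[match(vapply(results,
                                     function(r) r$classification$site_id, ""),
                              site_meta$site_id)]
  for (r in unique(rois)) {
    sel <- which(rois == r & pats %in% want)
    if (length(sel) < min_sites) next
    mats <- lapply(results[sel], function(x) {
      if (is.null(x[[slot]]))
        stop("ERBP matrices not kept; rerun classification with keep_erbp = TRUE")
      x[[slot]]
    })
    env <- grand_average_envelope(mats, window_ms, min_sites)
    rows[[r]] <- data.frame(roi = r, alignment = alignment,
                            time_ms = env$times_ms, mean_db = env$mean_db,
                            lo = env$ci_low, hi = env$ci_high,
                            n_sites = env$n_sites)
  }
  if (length(rows) == 0)
    return(data.frame(roi = character(), alignment = character(),
                      time_ms = numeric(), mean_db = numeric(),
                      lo = numeric(), hi = numeric(), n_sites = integer()))
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
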