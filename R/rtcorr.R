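#' Single-site power-to-RT rank correlation
#'
#' Spearman rank correlation (average ranks for ties) between per-trial
#' post-stimulus window ERBP means and reaction times. Negative values mean
#' greater post-stimulus high-gamma power goes with faster responses.
#'
#' @param post_means Per-trial post-stimulus ERBP means (dB).
#' @param rts Per-trial reaction times (ms), same trial order.
#' @param min_trials Minimum number of paired trials (default 5).
#' @return Spearman rho, or NA when either variable has constant ranks.
#' @export
site_spearman <- function(post_means, rts, min_trials = 5) {
  if (length(post_means) != length(rts))
    stop("post_means and rts must have the same length")
  ok <- !is.na(post_means) & !is.na(rts)
  if (sum(ok) < min_trials)
    stop("need at least ", min_trials, " paired trials")
  x <- post_means[ok]; y <- rts[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y, method = "spearman")
}

#' ROI-level tests of rho distributions against zero
#'
#' For every ROI with at least `min_sites` included sites (sites whose
#' pattern is stimulus-related or intermediate, i.e. significant
#' post-stimulus activation), the distribution of per-site rho values is
#' compared to zero with a two-tailed one-sample Wilcoxon signed-rank test
#' (exact for n <= 25 without ties or zeros, normal approximation otherwise;
#' zero-valued rhos are dropped, the signed-rank convention). BH correction
#' is applied across the tested ROIs.
#'
#' @param rho_table Data.frame with columns `roi` and `rho` (one row per
#'   included site).
#' @param min_sites Minimum included sites per ROI (default 10).
#' @return Data.frame with one row per tested ROI: `roi`, `n_sites`,
#'   `median_rho`, `p_raw`, `p_fdr`.
#' @export
roi_rho_test <- function(rho_table, min_sites = 10) {
  stopifnot(all(c("roi", "rho") %in% names(rho_table)))
  rho_table <- rho_table[is.finite(rho_table$rho), ]
  rows <- list()
  for (r in unique(rho_table$roi)) {
    rho <- rho_table$rho[rho_table$roi == r]
    if (length(rho) < min_sites) next
    nz <- rho[rho != 0]
    p <- if (length(nz) == 0) {
      warning("all rho values zero in ROI ", r)
      1
    } else {
      exact <- length(nz) <= 25 && !any(duplicated(abs(nz)))
      suppressWarnings(stats::wilcox.test(nz, mu = 0, exact = exact,
                                          correct = !exact)$p.value)
    }
    rows[[r]] <- data.frame(roi = r, n_sites = length(rho),
                            median_rho = stats::median(rho), p_raw = p)
  }
  if (length(rows) == 0)
    return(data.frame(roi = character(), n_sites = integer(),
                      median_rho = numeric(), p_raw = numeric(),
                      p_fdr = numeric()))
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res$p_fdr <- bh_fdr(res$p_raw)
  res
}

#' Build the per-site rho table from classification results
#'
#' Includes only sites with significant post-stimulus activation
#' (stimulus-related or intermediate pattern), the inclusion rule for the
#' RT-correlation analysis.
#'
#' @param results List of `hg_site_result` objects ([classify_channel()]).
#' @param site_meta Electrode metadata.
#' @return Data.frame: `site_id`, `roi`, `rho`, `n_trials`, `included`.
#' @export
site_rho_table <- function(results, site_meta) {
  rows <- lapply(results, function(r) {
    cl <- r$classification
    inc <- cl$pattern %in% c("stimulus", "intermediate")
    data.frame(site_id = cl$site_id,
               roi = site_meta$roi[match(cl$site_id, site_meta$site_id)],
               rho = if (inc) site_spearman(r$post_means, r$rt_ms)
                     else NA_real_,
               n_trials = cl$n_trials_used, included = inc)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
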