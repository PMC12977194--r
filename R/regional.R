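#' Tabulate pattern prevalence
#'
#' Counts and percentage prevalence of the stimulus-related, intermediate and
#' behavior-related patterns per scope cell: whole brain, ROI group, or ROI,
#' each split by hemisphere.
#'
#' @param classifications Data.frame with `site_id` and `pattern` (see
#'   [classification_table()]).
#' @param site_meta Electrode metadata (see [read_electrodes_table()]).
#' @param scope `"whole"`, `"roi_group"`, or `"roi"`.
#' @return Data.frame with one row per scope cell x hemisphere: `scope`,
#'   `hemisphere`, `n_total`, `n_stim`, `n_intermediate`, `n_behav`,
#'   `prev_stim_pct`, `prev_intermediate_pct`, `prev_behav_pct`, and
#'   per-pattern participant counts.
#' @export
tabulate_prevalence <- function(classifications, site_meta,
                                scope = c("roi_group", "whole", "roi")) {
  scope <- match.arg(scope)
  idx <- match(classifications$site_id, site_meta$site_id)
  if (anyNA(idx))
    stop("site(s) without metadata: ",
         paste(classifications$site_id[is.na(idx)], collapse = ", "))
  meta <- site_meta[idx, ]
  cell <- switch(scope, whole = rep("whole", nrow(meta)),
                 roi_group = meta$roi_group, roi = meta$roi)
  out <- list()
  for (cl in unique(cell)) for (h in c("L", "R")) {
    sel <- cell == cl & meta$hemisphere == h
    n <- sum(sel)
    pat <- classifications$pattern[sel]
    np <- function(p) length(unique(meta$participant_id[sel][pat == p]))
    row <- data.frame(scope = cl, hemisphere = h, n_total = n,
                      n_stim = sum(pat == "stimulus"),
                      n_intermediate = sum(pat == "intermediate"),
                      n_behav = sum(pat == "behavior"),
                      n_participants_stim = np("stimulus"),
                      n_participants_behav = np("behavior"))
    for (p in c("stim", "intermediate", "behav"))
      row[[paste0("prev_", p, "_pct")]] <-
        if (n > 0) 100 * row[[paste0("n_", p)]] / n else NA_real_
    out[[paste(cl, h)]] <- row
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Hemispheric Fisher exact comparison
#'
#' Two-sided Fisher exact test on the 2x2 table
#' `[[k_L, n_L - k_L], [k_R, n_R - k_R]]`. The sample (cross-product) odds
#' ratio with left-hemisphere odds in the numerator is reported as primary;
#' the conditional-MLE estimate and its 95% CI (from the exact test) are
#' reported alongside, since published odds ratios mix the two conventions.
#'
#' @param counts_L `c(k, n)` pattern count and total for the left hemisphere.
#' @param counts_R `c(k, n)` for the right hemisphere.
#' @return One-row data.frame: `k_L`, `n_L`, `k_R`, `n_R`, `odds_ratio`
#'   (sample), `odds_ratio_cmle`, `or_ci_low`, `or_ci_high`, `p_raw`.
#' @export
hemispheric_fisher <- function(counts_L, counts_R) {
  k_L <- counts_L[1]; n_L <- counts_L[2]
  k_R <- counts_R[1]; n_R <- counts_R[2]
  stopifnot(k_L <= n_L, k_R <= n_R, k_L >= 0, k_R >= 0)
  tab <- matrix(c(k_L, n_L - k_L, k_R, n_R - k_R), nrow = 2, byrow = TRUE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    return(data.frame(k_L = k_L, n_L = n_L, k_R = k_R, n_R = n_R,
                      odds_ratio = NA_real_, odds_ratio_cmle = NA_real_,
                      or_ci_low = NA_real_, or_ci_high = NA_real_, p_raw = 1))
  }
  ft <- stats::fisher.test(tab)
  or_sample <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  data.frame(k_L = k_L, n_L = n_L, k_R = k_R, n_R = n_R,
             odds_ratio = or_sample,
             odds_ratio_cmle = unname(ft$estimate),
             or_ci_low = ft$conf.int[1], or_ci_high = ft$conf.int[2],
             p_raw = ft$p.value)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false discovery rate adjustment; monotone and capped at 1.
#'
#' @param p_values Numeric vector of raw p-values in \[0, 1\].
#' @return Adjusted p-values, same order as the input.
#' @export
bh_fdr <- function(p_values) {
  stopifnot(all(p_values >= 0 & p_values <= 1))
  stats::p.adjust(p_values, method = "BH")
}

#' Hemispheric asymmetry across scope cells
#'
#' Runs [hemispheric_fisher()] for every scope cell and pattern in a
#' prevalence table and applies BH correction. With `fdr_family = "all"`
#' (default) all cell-by-pattern tests form one family; with
#' `"per_pattern"` each pattern is corrected separately.
#'
#' @param prevalence Output of [tabulate_prevalence()].
#' @param fdr_family `"all"` or `"per_pattern"`.
#' @return Data.frame with one row per scope cell x pattern, including
#'   `p_raw` and `p_fdr`.
#' @export
asymmetry_table <- function(prevalence, fdr_family = c("all", "per_pattern")) {
  fdr_family <- match.arg(fdr_family)
  cells <- unique(prevalence$scope)
  rows <- list()
  for (cl in cells) for (pat in c("stim", "intermediate", "behav")) {
    L <- prevalence[prevalence$scope == cl & prevalence$hemisphere == "L", ]
    R <- prevalence[prevalence$scope == cl & prevalence$hemisphere == "R", ]
    if (nrow(L) != 1 || nrow(R) != 1) next
    fr <- hemispheric_fisher(c(L[[paste0("n_", pat)]], L$n_total),
                             c(R[[paste0("n_", pat)]], R$n_total))
    rows[[paste(cl, pat)]] <- cbind(data.frame(scope = cl, pattern = pat), fr)
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  if (fdr_family == "all") {
    res$p_fdr <- bh_fdr(res$p_raw)
  } else {
    res$p_fdr <- NA_real_
    for (pat in unique(res$pattern)) {
      sel <- res$pattern == pat
      res$p_fdr[sel] <- bh_fdr(res$p_raw[sel])
    }
  }
  res
}

#' Stimulus/behavior balance index
#'
#' `(n_behav - n_stim) / (n_behav + n_stim)`: -1 for purely stimulus-related
#' ROIs, +1 for purely behavior-related, 0 for an even split. Undefined (NA)
#' when both counts are zero.
#'
#' @param n_stim Number of stimulus-related sites.
#' @param n_behav Number of behavior-related sites.
#' @return SB index in \[-1, 1\], or NA.
#' @export
#' @examples
#' sb_index(6, 22)    #  0.571...
#' sb_index(111, 1)   # -0.982...
sb_index <- function(n_stim, n_behav) {
  stopifnot(all(n_stim >= 0), all(n_behav >= 0))
  ifelse(n_stim + n_behav == 0, NA_real_,
         (n_behav - n_stim) / (n_behav + n_stim))
}

#' SB-index eligibility rule
#'
#' An ROI-by-hemisphere cell is eligible for an SB index when it has at least
#' `min_sites` sites showing either the stimulus- or behavior-related pattern
#' and those sites span at least `min_participants` distinct participants.
#'
#' @param patterns Character vector of site pattern labels in the cell.
#' @param participants Participant id per site (same length).
#' @param min_sites Minimum responsive-site count (default 5).
#' @param min_participants Minimum distinct participants (default 2).
#' @return Logical scalar.
#' @export
sb_eligibility <- function(patterns, participants, min_sites = 5,
                           min_participants = 2) {
  resp <- patterns %in% c("stimulus", "behavior")
  sum(resp) >= min_sites &&
    length(unique(participants[resp])) >= min_participants
}

#' Per-ROI SB index table
#'
#' @param classifications Site classification table.
#' @param site_meta Electrode metadata.
#' @param min_sites,min_participants Eligibility thresholds (see
#'   [sb_eligibility()]).
#' @return Data.frame with one row per ROI x hemisphere: totals, counts,
#'   number of contributing participants, `eligible`, and `sb_index` (NA when
#'   ineligible or undefined).
#' @export
sb_table <- function(classifications, site_meta, min_sites = 5,
                     min_participants = 2) {
  idx <- match(classifications$site_id, site_meta$site_id)
  meta <- site_meta[idx, ]
  rows <- list()
  for (r in unique(meta$roi)) for (h in c("L", "R")) {
    sel <- meta$roi == r & meta$hemisphere == h
    if (!any(sel)) next
    pat <- classifications$pattern[sel]
    elig <- sb_eligibility(pat, meta$participant_id[sel], min_sites,
                           min_participants)
    n_s <- sum(pat == "stimulus"); n_b <- sum(pat == "behavior")
    resp <- pat %in% c("stimulus", "behavior")
    rows[[paste(r, h)]] <- data.frame(
      roi = r, hemisphere = h, n_total = sum(sel),
      n_stim = n_s, n_behav = n_b,
      n_participants = length(unique(meta$participant_id[sel][resp])),
      eligible = elig,
      sb_index = if (elig) sb_index(n_s, n_b) else NA_real_)
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Two-sample coordinate asymmetry test
#'
#' Pooled-variance two-sample two-tailed t-test comparing dorsoventral MNI
#' z-coordinates between hemispheres.
#'
#' @param z_L Coordinates (mm) of left-hemisphere sites.
#' @param z_R Coordinates (mm) of right-hemisphere sites.
#' @return List with `t`, `p`, `df`, `mean_L`, `mean_R`.
#' @export
coord_asymmetry_test <- function(z_L, z_R) {
  if (length(z_L) < 2 || length(z_R) < 2)
    stop("need at least 2 coordinates per hemisphere")
  if (stats::sd(z_L) == 0 && stats::sd(z_R) == 0) {
    if (mean(z_L) == mean(z_R))
      return(list(t = 0, p = 1, df = length(z_L) + length(z_R) - 2,
                  mean_L = mean(z_L), mean_R = mean(z_R)))
    stop("degenerate variance in both samples")
  }
  tt <- stats::t.test(z_L, z_R, var.equal = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter), mean_L = mean(z_L), mean_R = mean(z_R))
}
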