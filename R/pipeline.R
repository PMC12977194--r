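#' Run the full analysis pipeline on a dataset directory
#'
#' Executes the five analysis stages on a dataset in the on-disk layout of
#' [simulate_dataset()] (per-participant `recording.bin` + `events.tsv`,
#' root-level `electrodes.tsv`): (1) preprocessing and site classification,
#' (2) behavioral summaries, (3) regional prevalence, hemispheric asymmetry
#' and SB indices, (4) RT correlation, (5) ROI envelopes. Every output table
#' is written as CSV together with a JSON manifest recording the
#' configuration, seed and per-stage row counts. Identical inputs produce
#' identical outputs.
#'
#' @param dataset_dir Dataset directory.
#' @param out_dir Output directory for result tables.
#' @param cfg An [analysis_config()].
#' @return Invisibly, a list with all result tables and the manifest.
#' @export
run_pipeline <- function(dataset_dir, out_dir, cfg = analysis_config()) {
  epath <- file.path(dataset_dir, "electrodes.tsv")
  if (!file.exists(epath))
    stop("validation error: missing electrodes.tsv in ", dataset_dir)
  pdirs <- list.dirs(dataset_dir, recursive = FALSE)
  pdirs <- pdirs[file.exists(file.path(pdirs, "events.tsv"))]
  if (length(pdirs) == 0)
    stop("validation error: no participant directories with events.tsv")
  electrodes <- read_electrodes_table(epath)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(config = unclass(cfg), stages = list())

  # stage 1: preprocess + classify
  results <- list()
  behav <- list()
  for (pd in pdirs) {
    p <- basename(pd)
    ev <- score_trials(read_events_table(file.path(pd, "events.tsv")))
    rec <- read_recording(file.path(pd, "recording.bin"),
                          block_id = paste0(p, "_block1"))
    res <- classify_recording(rec, ev, cfg, keep_erbp = TRUE)
    results <- c(results, res)
    behav[[p]] <- cbind(participant = p, behavioral_summary(ev))
  }
  cls <- classification_table(results)
  utils::write.csv(cls, file.path(out_dir, "site_classification.csv"),
                   row.names = FALSE)
  manifest$stages$classify <- list(n_sites = nrow(cls))

  # stage 2: behavior
  behav_df <- do.call(rbind, behav)
  utils::write.csv(behav_df, file.path(out_dir, "behavior_summary.csv"),
                   row.names = FALSE)
  manifest$stages$behavior <- list(n_participants = nrow(behav_df))

  # stage 3: regional statistics
  prev <- tabulate_prevalence(cls, electrodes, "roi_group")
  asym <- asymmetry_table(prev, cfg$fdr_family)
  sb <- sb_table(cls, electrodes, cfg$sb_min_sites, cfg$sb_min_participants)
  utils::write.csv(prev, file.path(out_dir, "prevalence.csv"),
                   row.names = FALSE)
  utils::write.csv(asym, file.path(out_dir, "asymmetry.csv"),
                   row.names = FALSE)
  utils::write.csv(sb, file.path(out_dir, "sb_index.csv"), row.names = FALSE)
  manifest$stages$regional <- list(n_cells = nrow(prev), n_tests = nrow(asym),
                                   n_sb = nrow(sb))

  # stage 4: RT correlation
  rho <- site_rho_table(results, electrodes)
  roi_tests <- roi_rho_test(rho[rho$included, ], cfg$roi_min_sites_rho)
  utils::write.csv(rho, file.path(out_dir, "rt_correlation_sites.csv"),
                   row.names = FALSE)
  utils::write.csv(roi_tests, file.path(out_dir, "rt_correlation_rois.csv"),
                   row.names = FALSE)
  manifest$stages$rt_correlation <- list(n_sites = sum(rho$included),
                                         n_rois = nrow(roi_tests))

  # stage 5: ROI envelopes
  env_stim <- roi_envelopes(results, electrodes, "stimulus",
                            cfg$envelope_window_ms,
                            cfg$roi_min_sites_envelope)
  env_press <- roi_envelopes(results, electrodes, "press",
                             cfg$envelope_press_window_ms,
                             cfg$roi_min_sites_envelope)
  env_all <- rbind(env_stim, env_press)
  utils::write.csv(env_all, file.path(out_dir, "roi_envelopes.csv"),
                   row.names = FALSE)
  manifest$stages$envelopes <- list(n_rois = length(unique(env_all$roi)))

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(classification = cls, behavior = behav_df,
                 prevalence = prev, asymmetry = asym, sb = sb,
                 rho_sites = rho, rho_rois = roi_tests,
                 envelopes = env_all, manifest = manifest))
}

#' Waterfall plot of single-trial ERBP
#'
#' Heatmap of single-trial stimulus-aligned ERBP with hit trials sorted by
#' reaction time (fastest at the top) and miss trials appended below a
#' separator; each hit's reaction time is overplotted.
#'
#' @param erbp A stimulus-aligned `hg_erbp` matrix.
#' @param events Scored events data.frame the matrix's `trial_index` points
#'   into.
#' @param file Optional output path (PNG or SVG by extension); when `NULL`
#'   the ggplot object is returned without writing.
#' @return The ggplot object, invisibly when written to file.
#' @export
render_waterfall <- function(erbp, events, file = NULL) {
  stopifnot(inherits(erbp, "hg_erbp"), erbp$alignment == "stimulus")
  out <- events[erbp$trial_index, ]
  is_hit <- out$outcome == "hit"
  if (!any(is_hit))
    warning("no hit trials; rendering misses only")
  ord <- c(which(is_hit)[order(out$rt_ms[is_hit])], which(!is_hit))
  vals <- erbp$values[ord, , drop = FALSE]
  df <- expand.grid(time_ms = erbp$times_ms, row = seq_along(ord))
  df$erbp <- as.vector(t(vals))
  df$rt_ms <- out$rt_ms[ord][df$row]
  n_hit <- sum(is_hit)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time_ms, y = .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$erbp)) +
    ggplot2::scale_fill_gradient2(low = "navy", mid = "white",
                                  high = "firebrick", name = "ERBP (dB)") +
    ggplot2::geom_point(data = df[!duplicated(df$row) & !is.na(df$rt_ms), ],
                        ggplot2::aes(x = .data$rt_ms, y = .data$row),
                        shape = 18, size = 1) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "Time from stimulus onset (ms)",
                  y = "Trial (sorted by RT; misses below)",
                  title = erbp$site_id)
  if (n_hit > 0 && n_hit < length(ord))
    p <- p + ggplot2::geom_hline(yintercept = n_hit + 0.5, linewidth = 0.8)
  if (!is.null(file)) {
    ggplot2::ggsave(file, p, width = 6, height = 4, dpi = 150)
    return(invisible(p))
  }
  p
}
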