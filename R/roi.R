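#' Auditory-centric ROI parcellation
#'
#' The 51-region parcellation used throughout the package, organised into nine
#' groups running from core auditory cortex (posteromedial Heschl's gyrus,
#' HGPM) through superior temporal plane (STP), lateral superior temporal
#' gyrus (STG), ventral and dorsal auditory-related streams, limbic and
#' prefrontal cortex, sensorimotor cortex, and a residual "Other" group.
#' Electrode tables must use these ROI labels; the group assignment is fixed.
#'
#' @return A data.frame with columns `roi`, `roi_group` and `roi_name`
#'   (one row per ROI, 51 rows).
#' @export
#' @examples
#' tab <- roi_table()
#' nrow(tab)            # 51
#' table(tab$roi_group)
roi_table <- function() {
  tab <- rbind(
    c("HGPM",   "Auditory core", "Heschl's gyrus, posteromedial portion"),
    c("HGAL",   "STP",           "Heschl's gyrus, anterolateral portion"),
    c("PP",     "STP",           "Planum polare"),
    c("PT",     "STP",           "Planum temporale"),
    c("STGM",   "STG",           "Superior temporal gyrus, middle portion"),
    c("STGP",   "STG",           "Superior temporal gyrus, posterior portion"),
    c("MTGA",   "Ventral",       "Middle temporal gyrus, anterior portion"),
    c("MTGM",   "Ventral",       "Middle temporal gyrus, middle portion"),
    c("MTGP",   "Ventral",       "Middle temporal gyrus, posterior portion"),
    c("STGA",   "Ventral",       "Superior temporal gyrus, anterior portion"),
    c("STSL",   "Ventral",       "Superior temporal sulcus, lower bank"),
    c("STSU",   "Ventral",       "Superior temporal sulcus, upper bank"),
    c("AG",     "Dorsal",        "Angular gyrus"),
    c("SMG",    "Dorsal",        "Supramarginal gyrus"),
    c("Amyg",   "Limbic",        "Amygdala"),
    c("Hipp",   "Limbic",        "Hippocampus"),
    c("PHG",    "Limbic",        "Parahippocampal gyrus"),
    c("ACC",    "Prefrontal",    "Anterior cingulate cortex"),
    c("FP",     "Prefrontal",    "Frontal pole"),
    c("GR",     "Prefrontal",    "Gyrus rectus"),
    c("IFGop",  "Prefrontal",    "Inferior frontal gyrus, pars opercularis"),
    c("IFGor",  "Prefrontal",    "Inferior frontal gyrus, pars orbitalis"),
    c("IFGtr",  "Prefrontal",    "Inferior frontal gyrus, pars triangularis"),
    c("MFG",    "Prefrontal",    "Middle frontal gyrus"),
    c("OG",     "Prefrontal",    "Orbital gyri"),
    c("SFG",    "Prefrontal",    "Superior frontal gyrus"),
    c("SubcG",  "Prefrontal",    "Subcallosal gyrus"),
    c("ParaCL", "Sensorimotor",  "Paracentral lobule"),
    c("PostCG", "Sensorimotor",  "Postcentral gyrus"),
    c("PreCG",  "Sensorimotor",  "Precentral gyrus"),
    c("CingMA", "Other",         "Cingulate cortex, middle anterior portion"),
    c("CingMP", "Other",         "Cingulate cortex, middle posterior portion"),
    c("CingPD", "Other",         "Cingulate cortex, posterior dorsal portion"),
    c("Cun",    "Other",         "Cuneus"),
    c("FG",     "Other",         "Fusiform gyrus"),
    c("IOG",    "Other",         "Inferior occipital gyrus"),
    c("ITGA",   "Other",         "Inferior temporal gyrus, anterior portion"),
    c("ITGM",   "Other",         "Inferior temporal gyrus, middle portion"),
    c("ITGP",   "Other",         "Inferior temporal gyrus, posterior portion"),
    c("InsA",   "Other",         "Anterior insula"),
    c("InsP",   "Other",         "Posterior insula"),
    c("LingG",  "Other",         "Lingual gyrus"),
    c("MOG",    "Other",         "Middle occipital gyrus"),
    c("OP",     "Other",         "Occipital pole"),
    c("PMC",    "Other",         "Premotor cortex"),
    c("PreCun", "Other",         "Precuneus"),
    c("SOG",    "Other",         "Superior orbital gyrus"),
    c("SPL",    "Other",         "Superior parietal lobule"),
    c("TP",     "Other",         "Temporal pole"),
    c("VStr",   "Other",         "Ventral striatum"),
    c("POp",    "Other",         "Parietal operculum"))
  data.frame(roi = tab[, 1], roi_group = tab[, 2], roi_name = tab[, 3],
             stringsAsFactors = FALSE)
}

#' Map ROI labels to ROI groups
#'
#' @param roi Character vector of ROI labels.
#' @return Character vector of ROI group names.
#' @export
roi_group_of <- function(roi) {
  tab <- roi_table()
  idx <- match(roi, tab$roi)
  if (anyNA(idx)) {
    bad <- unique(roi[is.na(idx)])
    stop("Unknown ROI label(s): ", paste(bad, collapse = ", "),
         ". Valid labels are: ", paste(tab$roi, collapse = ", "))
  }
  tab$roi_group[idx]
}

#' Activity pattern labels
#'
#' The four site-level activity pattern labels assigned by
#' [classify_site()]: significant high-gamma power only after the stimulus,
#' only before the button press, in both windows, or in neither.
#' @return Character vector of the four labels in canonical order.
#' @export
pattern_levels <- function() c("stimulus", "behavior", "intermediate", "none")
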