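#' AAL-90 region labels
#'
#' The 90 cerebral regions of the Anatomical Automatic Labeling atlas in
#' standard order (odd indices left hemisphere, even indices right), used as
#' default node labels so that outputs name regions the way the clinical
#' literature does (e.g. `"Fusiform_R"`, `"Pallidum_R"`).
#'
#' @return Character vector of length 90.
#' @export
#' @examples
#' aal90_labels()[c(46, 56, 76, 80)]
aal90_labels <- function() {
  base <- c(
    "Precentral", "Frontal_Sup", "Frontal_Sup_Orb", "Frontal_Mid",
    "Frontal_Mid_Orb", "Frontal_Inf_Oper", "Frontal_Inf_Tri",
    "Frontal_Inf_Orb", "Rolandic_Oper", "Supp_Motor_Area", "Olfactory",
    "Frontal_Sup_Medial", "Frontal_Med_Orb", "Rectus", "Insula",
    "Cingulum_Ant", "Cingulum_Mid", "Cingulum_Post", "Hippocampus",
    "ParaHippocampal", "Amygdala", "Calcarine", "Cuneus", "Lingual",
    "Occipital_Sup", "Occipital_Mid", "Occipital_Inf", "Fusiform",
    "Postcentral", "Parietal_Sup", "Parietal_Inf", "SupraMarginal",
    "Angular", "Precuneus", "Paracentral_Lobule", "Caudate", "Putamen",
    "Pallidum", "Thalamus", "Heschl", "Temporal_Sup", "Temporal_Pole_Sup",
    "Temporal_Mid", "Temporal_Pole_Mid", "Temporal_Inf")
  paste0(rep(base, each = 2L), c("_L", "_R"))
}

# default labels for n regions: AAL-90 when n == 90, else generic V1..Vn
default_region_labels <- function(n) {
  if (n == 90L) aal90_labels() else sprintf("V%d", seq_len(n))
}
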