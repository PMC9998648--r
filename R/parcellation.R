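#' Default 90-region AAL parcellation labels
#'
#' Returns the ordered labels of the 90 cortical and subcortical regions of
#' the Automated Anatomical Labeling (AAL) atlas, in standard AAL order
#' (left/right interleaved), with cerebellar and vermis regions excluded.
#' This ordering is the positional reference for every ROI-indexed structure
#' in the package; any atlas can be substituted by passing a different
#' character vector of unique labels wherever a parcellation is expected.
#'
#' @return Character vector of length 90.
#' @export
#' @examples
#' length(aal90_labels())
#' head(aal90_labels())
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
    "Temporal_Mid", "Temporal_Pole_Mid", "Temporal_Inf"
  )
  as.vector(rbind(paste0(base, "_L"), paste0(base, "_R")))
}

# Validate a parcellation label vector: unique, non-empty, length >= 2.
check_parcellation <- function(labels) {
  if (!is.character(labels) || length(labels) < 2L)
    stop("parcellation must be a character vector with at least 2 ROI labels")
  if (anyDuplicated(labels))
    stop("parcellation labels must be unique")
  if (any(!nzchar(labels)))
    stop("parcellation labels must be non-empty strings")
  labels
}
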