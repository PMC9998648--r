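# Synthetic placeholder RSN-to-ROI map for the 90-region AAL parcellation.
# These assignments follow common usage in the resting-state literature and
# are meant as editable defaults, NOT as a validated atlas: replace this file
# with your own network definitions for any substantive analysis.
SAL:
  - Insula_L
  - Insula_R
  - Cingulum_Ant_L
  - Cingulum_Ant_R
  - Cingulum_Mid_L
  - Cingulum_Mid_R
DMN:
  - Frontal_Med_Orb_L
  - Frontal_Med_Orb_R
  - Frontal_Sup_Medial_L
  - Frontal_Sup_Medial_R
  - Cingulum_Post_L
  - Cingulum_Post_R
  - Precuneus_L
  - Precuneus_R
  - Angular_L
  - Angular_R
  - Hippocampus_L
  - Hippocampus_R
  - Temporal_Mid_L
  - Temporal_Mid_R
CEN:
  - Frontal_Sup_L
  - Frontal_Sup_R
  - Frontal_Mid_L
  - Frontal_Mid_R
  - Parietal_Sup_L
  - Parietal_Sup_R
  - Parietal_Inf_L
  - Parietal_Inf_R
MOT:
  - Precentral_L
  - Precentral_R
  - Postcentral_L
  - Postcentral_R
  - Supp_Motor_Area_L
  - Supp_Motor_Area_R
  - Paracentral_Lobule_L
  - Paracentral_Lobule_R
VIS:
  - Calcarine_L
  - Calcarine_R
  - Cuneus_L
  - Cuneus_R
  - Lingual_L
  - Lingual_R
  - Occipital_Sup_L
  - Occipital_Sup_R
  - Occipital_Mid_L
  - Occipital_Mid_R
  - Occipital_Inf_L
  - Occipital_Inf_R
  - Fusiform_L
  - Fusiform_R
AUD:
  - Heschl_L
  - Heschl_R
  - Temporal_Sup_L
  - Temporal_Sup_R
  - Rolandic_Oper_L
  - Rolandic_Oper_R
BG:
  - Caudate_L
  - Caudate_R
  - Putamen_L
  - Putamen_R
  - Pallidum_L
  - Pallidum_R
  - Thalamus_L
  - Thalamus_R
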