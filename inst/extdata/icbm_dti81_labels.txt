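# ICBM-DTI-81 white-matter atlas: 48 region labels, one per line.
middle_cerebellar_peduncle
pontine_crossing_tract
genu_of_corpus_callosum
body_of_corpus_callosum
splenium_of_corpus_callosum
fornix_column_and_body
corticospinal_tract_R
corticospinal_tract_L
medial_lemniscus_R
medial_lemniscus_L
inferior_cerebellar_peduncle_R
inferior_cerebellar_peduncle_L
superior_cerebellar_peduncle_R
superior_cerebellar_peduncle_L
cerebral_peduncle_R
cerebral_peduncle_L
anterior_limb_of_internal_capsule_R
anterior_limb_of_internal_capsule_L
posterior_limb_of_internal_capsule_R
posterior_limb_of_internal_capsule_L
retrolenticular_part_of_internal_capsule_R
retrolenticular_part_of_internal_capsule_L
anterior_corona_radiata_R
anterior_corona_radiata_L
superior_corona_radiata_R
superior_corona_radiata_L
posterior_corona_radiata_R
posterior_corona_radiata_L
posterior_thalamic_radiation_R
posterior_thalamic_radiation_L
sagittal_stratum_R
sagittal_stratum_L
external_capsule_R
external_capsule_L
cingulum_cingulate_gyrus_R
cingulum_cingulate_gyrus_L
cingulum_hippocampus_R
cingulum_hippocampus_L
fornix_cres_stria_terminalis_R
fornix_cres_stria_terminalis_L
superior_longitudinal_fasciculus_R
superior_longitudinal_fasciculus_L
superior_fronto_occipital_fasciculus_R
superior_fronto_occipital_fasciculus_L
uncinate_fasciculus_R
uncinate_fasciculus_L
tapetum_R
tapetum_L
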