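{"seed":20,"n_seizures":7,"n_frames":6000,"n_ictal_frames":333,"n_rois":20,"n_quiet":2,"frac_ictal_low":0.357142857142857,"frac_ictal_high":0.0714285714285714,"frac_neutral":0.571428571428571,"mean_ictal_dff":3.06734083414341,"mean_interictal_dff":4.96864556999634,"frac_participant_onset":0,"frac_participant_offset":0,"corr_interictal_neuron":0.0973237847478051,"corr_ictal_neuron":0.11385358518338,"corr_interictal_neuropil":0.795720880304253,"corr_ictal_neuropil":0.766774174409381,"rate_class_agreement":0.944444444444444}
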