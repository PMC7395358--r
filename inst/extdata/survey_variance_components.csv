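outcome,var_cluster,var_household
blood_test,0.394,0.385
aware_hiv,0.696,0.039
aware_campaign,0.851,0.067
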