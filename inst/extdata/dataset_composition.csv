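data_source,n_samples,imu,data_use,phase
supplemental_a,4910,no,training,one
supplemental_b,13913,no,training,one
pi_dataset,2458,yes,training_and_testing,one
phase_two_left,763,yes,training_and_testing,two
phase_two_right,617,yes,training_and_testing,two
phase_two_supine,622,yes,none,none
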