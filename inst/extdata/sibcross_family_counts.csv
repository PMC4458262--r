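# Fertile/sterile counts of the published two-gene GMS characterization families
family_id,fertile,sterile
F1_a,11,19
F1_b,1,2
F1_c,3,0
F2_a,51,27
F2_b,26,16
F2_c,25,11
F2_d,76,18
F2_e,45,20
F2_f,399,35
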