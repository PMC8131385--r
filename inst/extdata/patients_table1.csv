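patient_id,years_post_onset,age_at_testing,l2_aoa,pct_lifetime_L1,pct_lifetime_L2,pct_use_L1,pct_use_L2,bnt_L1,bnt_L2,papt,treated_language,n_sessions
P1,7,44,19,72,28,78,22,26,22,48,L2,10
P2,14,37,7.5,26,74,34,66,7,25,49,L1,13
P3,1,66,45,87,13,98,2,9,0,27,L2,17
P4,0,34,12,71,29,54,46,0,0,52,L2,10
P5,6,55,0,25,75,6,94,1,0,43,L2,18
P6,13,54,21,55,45,50,50,27,28,47,L1,9
P7,1,56,5,37,63,42,58,11,25,48,L1,10
P8,1,54,6,34,66,45,55,4,31,45,L2,7
P9,2,73,17,66,34,100,0,19,17,40,L1,10
P10,1,86,69,95,5,70,30,0,0,37,L1,10
P11,1,89,5,28,72,1,99,0,1,25,L2,10
P12,0,42,18,90,10,71,29,28,3,43,L1,10
P13,0,42,9,68,32,71,29,1,0,47,L1,10
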