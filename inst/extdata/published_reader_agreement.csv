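section,pair,kappa,se,discrepant_pct
intra_without_asc,R1,0.971,0.006,1.44
intra_without_asc,R2,0.952,0.007,2.41
intra_without_asc,R3,0.949,0.008,2.53
intra_with_asc,R1,0.967,0.006,1.67
intra_with_asc,R2,0.952,0.007,2.41
intra_with_asc,R3,0.949,0.008,2.53
without_vs_with_asc,R1,0.978,0.005,1.09
without_vs_with_asc,R2,0.961,0.007,1.95
without_vs_with_asc,R3,0.961,0.007,1.95
between_without_asc,R1_R2,0.967,0.006,1.67
between_without_asc,R1_R3,0.924,0.009,3.79
between_without_asc,R2_R3,0.946,0.008,2.70
between_with_asc,R1_R2,0.947,0.008,2.64
between_with_asc,R1_R3,0.921,0.009,3.97
between_with_asc,R2_R3,0.941,0.008,2.93
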