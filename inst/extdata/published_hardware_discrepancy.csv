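setting,n,visual_discrepant,automatic_discrepant
ecam_lehr,704,12,12
symbia_lehr,147,3,2
symbia_fanbeam,457,3,8
anyscan_lehrhs,432,7,9
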