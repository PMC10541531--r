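arm,M1,SD1,M2,SD2,d,c
no_asc,0.389,0.135,1.264,0.300,3.760,0.661
asc,0.579,0.157,1.577,0.320,3.958,0.907
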