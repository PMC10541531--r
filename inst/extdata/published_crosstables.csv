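method,n11,n12,n21,n22
visual,893,15,10,822
automatic,944,25,6,765
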