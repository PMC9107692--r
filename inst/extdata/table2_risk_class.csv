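subtype,n,ror_low,ror_medium,ror_high,rs_low,rs_medium,rs_high
LumA,62,44,18,0,51,10,1
LumB,17,0,15,2,10,6,1
Basal,6,0,2,4,1,2,3
HER2E,2,0,2,0,0,1,1
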