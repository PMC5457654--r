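subgroup,n,prop
S1,66,19.7
S2,219,8.2
S3,31,0.0
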