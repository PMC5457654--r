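subgroup,n,prop,prop_table
S1,32,56.3,32.8
S2,68,17.6,17.6
S3,55,45.5,45.5
S4,74,27.0,27.0
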