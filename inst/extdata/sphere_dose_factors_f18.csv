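mass_g,dose_factor_mGy_per_MBq
1.42,268
3.7,105
4,97.3
8,50
18.62,22.4
22.8,18.5
24.9,17
46.61,9.4
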