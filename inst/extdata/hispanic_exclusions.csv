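state_prefix,year_start,year_end,race_ethnicity
22,1990,1990,H
33,1990,1992,H
40,1990,1996,H
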