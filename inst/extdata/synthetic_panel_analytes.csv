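analyte,lower_limit_pg_ml,upper_limit_pg_ml,dilution_factor
A_low,4,1000,2
B_keep,6,1000,1
C_high,10,500,2
D_full,1,1000,1
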