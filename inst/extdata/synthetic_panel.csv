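patient_id,cohort,pfi_days,A_low,B_keep,C_high,D_full
P01,NACT,30,<LOD,<LOD,>ULOQ,110
P02,NACT,60,<LOD,<LOD,200,120
P03,NACT,90,<LOD,30,300,130
P04,NACT,120,50,40,400,140
P05,NACT,150,60,50,500,150
P06,NACT,180,70,60,600,160
P07,NACT,220,80,70,700,170
P08,NACT,260,90,80,800,180
P09,NACT,320,100,90,900,190
P10,NACT,400,110,100,950,200
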