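fl_lower_cm,fl_upper_cm,rate_cm_per_yr
50,110,30
110,150,25
150,180,18
180,230,18
230,265,14
265,300,8
300,400,4
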