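"chemical","ban_year","t_double_in","t_half_in","peak_intake","t_half_elim","target_age"
"BDE47",1995,5,6.8,1,2.2,30
"DDT",1970,10,5,500,2,30
"PCB153",1972,15,10,15,15,30
"HCB",1975,15,12,5,6,30
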