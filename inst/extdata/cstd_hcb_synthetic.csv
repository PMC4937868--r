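"year","age","conc_ng_per_g_lipid","n"
1996,30,21.9428140504095,NA
1998,30,19.7329280902051,NA
2000,30,17.7048697947193,NA
2002,30,15.8626240942528,NA
2004,30,14.2018987424147,NA
2006,30,12.7121687297437,NA
2008,30,11.3724949917108,NA
2010,30,10.1684034787648,NA
2012,30,9.08720362586309,NA
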