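"year","age","conc_ng_per_g_lipid","n"
2004,30,2.09990292322354,NA
2005,30,1.9260405424798,NA
2006,30,1.76055590048486,NA
2007,30,1.60498434195741,NA
2008,30,1.46007491587476,NA
2009,30,1.32601916954618,NA
2010,30,1.20264120036061,NA
2011,30,1.08954971851326,NA
2012,30,0.986267817642688,NA
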