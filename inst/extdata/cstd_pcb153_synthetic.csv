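"year","age","conc_ng_per_g_lipid","n"
1996,30,107.711581794164,NA
1998,30,96.9676487882175,NA
2000,30,87.1965179655148,NA
2002,30,78.4862545299781,NA
2004,30,70.6899378010289,NA
2006,30,63.6184746028641,NA
2008,30,57.1958058855789,NA
2010,30,51.3534396244839,NA
2012,30,46.0296037079022,NA
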