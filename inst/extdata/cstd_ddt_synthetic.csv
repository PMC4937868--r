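"year","age","conc_ng_per_g_lipid","n"
1980,30,683.638281613629,NA
1982,30,528.984489457673,NA
1984,30,405.974634605187,NA
1986,30,309.926959740985,NA
1988,30,235.825815868227,NA
1990,30,179.109609133337,NA
1992,30,135.896891124648,NA
1994,30,103.053117178805,NA
1996,30,78.1244037588931,NA
1998,30,59.2176711746079,NA
2000,30,44.8841257150627,NA
2002,30,34.018942911532,NA
2004,30,25.7831032754726,NA
2006,30,19.5407181729568,NA
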