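"year","intake_ng_per_kg_bw_per_day"
1965,0.015625
1966,0.0179484117968287
1967,0.0206173111058265
1968,0.023683071351725
1969,0.0272047051030039
1970,0.03125
1971,0.0358968235936573
1972,0.041234622211653
1973,0.0473661427034499
1974,0.0544094102060078
1975,0.0625
1976,0.0717936471873147
1977,0.0824692444233059
1978,0.0947322854068999
1979,0.108818820412016
1980,0.125
1981,0.143587294374629
1982,0.164938488846612
1983,0.1894645708138
1984,0.217637640824031
1985,0.25
1986,0.287174588749259
1987,0.329876977693224
1988,0.3789291416276
1989,0.435275281648062
1990,0.5
1991,0.574349177498517
1992,0.659753955386447
1993,0.757858283255199
1994,0.870550563296124
1995,1
1996,0.90308968739698
1997,0.815570983482775
1998,0.736533744523507
1999,0.665156029099061
2000,0.600695550389288
2001,0.542481956821819
2002,0.489909860804718
2003,0.442432543046831
2004,0.399556266994413
2005,0.360835144257489
2006,0.32586649762934
2007,0.294286673477229
2008,0.265767259955648
2009,0.240011671713698
2010,0.21675206557955
2011,0.195746555146886
2012,0.176776695296637
2013,0.159645210494511
2014,0.144173943239913
2015,0.130202001331323
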