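"year","intake_ng_per_kg_bw_per_day"
1940,62.5
1941,66.9858414085183
1942,71.7936471873147
1943,76.9465258340573
1944,82.4692444233059
1945,88.3883476483184
1946,94.7322854068999
1947,101.531549544529
1948,108.818820412015
1949,116.629123942101
1950,125
1951,133.971682817037
1952,143.587294374629
1953,153.893051668115
1954,164.938488846612
1955,176.776695296637
1956,189.4645708138
1957,203.063099089059
1958,217.637640824031
1959,233.258247884202
1960,250
1961,267.943365634073
1962,287.174588749259
1963,307.786103336229
1964,329.876977693224
1965,353.553390593274
1966,378.9291416276
1967,406.126198178118
1968,435.275281648062
1969,466.516495768404
1970,500
1971,435.275281648062
1972,378.9291416276
1973,329.876977693224
1974,287.174588749259
1975,250
1976,217.637640824031
1977,189.4645708138
1978,164.938488846612
1979,143.587294374629
1980,125
1981,108.818820412015
1982,94.7322854068999
1983,82.4692444233059
1984,71.7936471873147
1985,62.5
1986,54.4094102060077
1987,47.3661427034499
1988,41.2346222116529
1989,35.8968235936573
1990,31.25
1991,27.2047051030039
1992,23.683071351725
1993,20.6173111058265
1994,17.9484117968287
1995,15.625
1996,13.6023525515019
1997,11.8415356758625
1998,10.3086555529132
1999,8.97420589841434
2000,7.8125
2001,6.80117627575097
2002,5.92076783793124
2003,5.15432777645662
2004,4.48710294920717
2005,3.90625
2006,3.40058813787548
2007,2.96038391896562
2008,2.57716388822831
2009,2.24355147460358
2010,1.953125
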