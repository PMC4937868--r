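"year","intake_ng_per_kg_bw_per_day"
1945,1.25
1946,1.30911765352578
1947,1.37103122461828
1948,1.43587294374629
1949,1.50378129510265
1950,1.57490131236859
1951,1.64938488846612
1952,1.72739109995972
1953,1.80908654680047
1954,1.894645708138
1955,1.98425131496025
1956,2.07809474035697
1957,2.17637640824031
1958,2.27930622139554
1959,2.38710400977604
1960,2.5
1961,2.61823530705157
1962,2.74206244923656
1963,2.87174588749259
1964,3.00756259020529
1965,3.14980262473718
1966,3.29876977693224
1967,3.45478219991944
1968,3.61817309360095
1969,3.78929141627599
1970,3.9685026299205
1971,4.15618948071394
1972,4.35275281648062
1973,4.55861244279108
1974,4.77420801955208
1975,5
1976,4.71937156340847
1977,4.4544935907017
1978,4.20448207626857
1979,3.9685026299205
1980,3.7457676921917
1981,3.53553390593274
1982,3.33709963542509
1983,3.14980262473718
1984,2.9730177875068
1985,2.80615512077343
1986,2.64865773589824
1987,2.5
1988,2.35968578170423
1989,2.22724679535085
1990,2.10224103813429
1991,1.98425131496025
1992,1.87288384609585
1993,1.76776695296637
1994,1.66854981771254
1995,1.57490131236859
1996,1.4865088937534
1997,1.40307756038672
1998,1.32432886794912
1999,1.25
2000,1.17984289085212
2001,1.11362339767542
2002,1.05112051906714
2003,0.992125657480125
2004,0.936441923047926
2005,0.883883476483184
2006,0.834274908856271
2007,0.787450656184296
2008,0.743254446876701
2009,0.701538780193358
2010,0.66216443397456
2011,0.625
2012,0.589921445426058
2013,0.556811698837712
2014,0.525560259533572
2015,0.496062828740062
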