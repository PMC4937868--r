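"year","intake_ng_per_kg_bw_per_day"
1940,3.41895933209331
1941,3.58065601466406
1942,3.75
1943,3.92735296057735
1944,4.11309367385485
1945,4.30761883123888
1946,4.51134388530794
1947,4.72470393710577
1948,4.94815466539835
1949,5.18217329987916
1950,5.42725964040142
1951,5.68393712441399
1952,5.95275394488075
1953,6.23428422107091
1954,6.52912922472093
1955,6.83791866418663
1956,7.16131202932812
1957,7.5
1958,7.8547059211547
1959,8.22618734770969
1960,8.61523766247776
1961,9.02268777061587
1962,9.44940787421155
1963,9.89630933079671
1964,10.3643465997583
1965,10.8545192808028
1966,11.367874248828
1967,11.9055078897615
1968,12.4685684421418
1969,13.0582584494419
1970,13.6758373283733
1971,14.3226240586562
1972,15
1973,13.9954948730521
1974,13.0582584494419
1975,12.1837859453435
1976,11.367874248828
1977,10.6066017177982
1978,9.89630933079671
1979,9.23358310008687
1980,8.61523766247776
1981,8.0383009690222
1982,7.5
1983,6.99774743652606
1984,6.52912922472093
1985,6.09189297267177
1986,5.68393712441399
1987,5.30330085889911
1988,4.94815466539835
1989,4.61679155004344
1990,4.30761883123888
1991,4.0191504845111
1992,3.75
1993,3.49887371826303
1994,3.26456461236047
1995,3.04594648633588
1996,2.841968562207
1997,2.65165042944955
1998,2.47407733269918
1999,2.30839577502172
2000,2.15380941561944
2001,2.00957524225555
2002,1.875
2003,1.74943685913151
2004,1.63228230618023
2005,1.52297324316794
2006,1.4209842811035
2007,1.32582521472478
2008,1.23703866634959
2009,1.15419788751086
2010,1.07690470780972
2011,1.00478762112777
2012,0.9375
2013,0.874718429565757
2014,0.816141153090116
2015,0.761486621583971
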