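year,delta_c14_permil
1930,0
1931,0
1932,0
1933,0
1934,0
1935,0
1936,0
1937,0
1938,0
1939,0
1940,0
1941,0
1942,0
1943,0
1944,0
1945,0
1946,0
1947,0
1948,0
1949,0
1950,0
1951,0
1952,0
1953,0
1954,0
1955,0
1956,25
1957,60
1958,110
1959,180
1960,210
1961,215
1962,380
1963,700
1964,850
1965,780
1966,700
1967,650
1968,600
1969,560
1970,525
1971,495
1972,460
1973,430
1974,405
1975,380
1976,355
1977,330
1978,310
1979,290
1980,270
1981,250
1982,235
1983,220
1984,205
1985,190
1986,180
1987,170
1988,160
1989,150
1990,140
1991,130
1992,122
1993,115
1994,108
1995,100
1996,95
1997,90
1998,85
1999,80
2000,75
2001,70
2002,65
2003,60
2004,57
2005,54
2006,51
2007,48
2008,46
2009,44
2010,42
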