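year,pairs,fledged,breeding_success,juvenile_survival,return_rate
1972,2300,NA,NA,NA,NA
1981,NA,NA,NA,0.69,NA
1982,NA,NA,NA,0.70,NA
1983,NA,NA,NA,0.66,NA
1984,NA,NA,NA,0.85,NA
1985,NA,NA,NA,0.72,NA
1986,NA,NA,NA,0.86,NA
1987,NA,NA,NA,0.57,NA
1988,3736,NA,NA,0.73,NA
1989,4057,NA,NA,NA,NA
1990,NA,NA,NA,0.48,NA
1991,NA,NA,NA,NA,NA
1992,NA,NA,NA,0.63,NA
1993,NA,NA,NA,0.67,NA
1994,NA,NA,NA,0.68,NA
1995,NA,NA,NA,0.29,NA
1996,NA,NA,NA,0.71,NA
1997,NA,NA,NA,0.48,NA
1998,3703,1889,0.51,0.30,NA
1999,3699,1517,0.41,0.30,NA
2000,4326,2033,0.47,0.24,0.96
2001,4797,2542,0.53,0.11,1
2002,4687,2437,0.52,0.09,0.98
2003,5145,2933,0.57,NA,1
2004,5640,2707,0.48,NA,1
2005,5614,2414,0.43,NA,1
2006,5074,1776,0.35,NA,0.9
2007,5134,2105,0.41,NA,0.9
2008,5212,2241,0.43,NA,0.9
2009,5233,2041,0.39,NA,0.95
2010,NA,NA,0.38,NA,0.93
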