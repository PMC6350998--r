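year,hatchlings
1966,61107
1967,51026
1968,48528
1969,43101
1970,40567
1971,29243
1972,26245
1973,24758
1974,25382
1975,19060
1976,15690
1977,17048
1978,15460
1979,12698
1980,11571
1981,9759
1982,11561
1983,9028
1984,8876
1985,7642
1986,7472
1987,9365
1988,9503
1989,11864
1990,12823
1991,15549
1992,20258
1993,23961
1994,31454
1995,40619
1996,50390
1997,65198
1998,78393
1999,106600
2000,131082
2001,145075
2002,180785
2003,196084
2004,217029
2005,263031
2006,239474
2007,301806
2008,322787
2009,336112
2010,348627
2011,328352
2012,289895
2013,351602
2014,341822
2015,347715
2016,330493
2017,359767
2018,327532
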