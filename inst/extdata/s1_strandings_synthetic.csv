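year,count
1982,1
1983,0
1984,2
1985,5
1986,3
1987,10
1988,7
1989,12
1990,8
1991,15
1992,9
1993,20
1994,13
1995,70
1996,24
1997,18
1998,30
1999,218
2000,34
2001,48
2002,160
2003,28
2004,55
2005,68
2006,42
2007,75
2008,88
2009,112
2010,148
2011,126
2012,242
2013,271
2014,1188
2015,480
2016,427
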