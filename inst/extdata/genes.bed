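chr1	0	10000	G00001
chr1	1e+05	110000	G00002
chr1	2e+05	210000	G00003
chr1	3e+05	310000	G00004
chr1	4e+05	410000	G00005
chr1	5e+05	510000	G00006
chr1	6e+05	610000	G00007
chr1	7e+05	710000	G00008
chr1	8e+05	810000	G00009
chr1	9e+05	910000	G00010
chr1	1e+06	1010000	G00011
chr1	1100000	1110000	G00012
chr1	1200000	1210000	G00013
chr1	1300000	1310000	G00014
chr1	1400000	1410000	G00015
chr1	1500000	1510000	G00016
chr1	1600000	1610000	G00017
chr1	1700000	1710000	G00018
chr1	1800000	1810000	G00019
chr1	1900000	1910000	G00020
chr2	0	10000	G00021
chr2	1e+05	110000	G00022
chr2	2e+05	210000	G00023
chr2	3e+05	310000	G00024
chr2	4e+05	410000	G00025
chr2	5e+05	510000	G00026
chr2	6e+05	610000	G00027
chr2	7e+05	710000	G00028
chr2	8e+05	810000	G00029
chr2	9e+05	910000	G00030
chr2	1e+06	1010000	G00031
chr2	1100000	1110000	G00032
chr2	1200000	1210000	G00033
chr2	1300000	1310000	G00034
chr2	1400000	1410000	G00035
chr2	1500000	1510000	G00036
chr2	1600000	1610000	G00037
chr2	1700000	1710000	G00038
chr2	1800000	1810000	G00039
chr2	1900000	1910000	G00040
chr3	0	10000	G00041
chr3	1e+05	110000	G00042
chr3	2e+05	210000	G00043
chr3	3e+05	310000	G00044
chr3	4e+05	410000	G00045
chr3	5e+05	510000	G00046
chr3	6e+05	610000	G00047
chr3	7e+05	710000	G00048
chr3	8e+05	810000	G00049
chr3	9e+05	910000	G00050
chr3	1e+06	1010000	G00051
chr3	1100000	1110000	G00052
chr3	1200000	1210000	G00053
chr3	1300000	1310000	G00054
chr3	1400000	1410000	G00055
chr3	1500000	1510000	G00056
chr3	1600000	1610000	G00057
chr3	1700000	1710000	G00058
chr3	1800000	1810000	G00059
chr3	1900000	1910000	G00060
chr4	0	10000	G00061
chr4	1e+05	110000	G00062
chr4	2e+05	210000	G00063
chr4	3e+05	310000	G00064
chr4	4e+05	410000	G00065
chr4	5e+05	510000	G00066
chr4	6e+05	610000	G00067
chr4	7e+05	710000	G00068
chr4	8e+05	810000	G00069
chr4	9e+05	910000	G00070
chr4	1e+06	1010000	G00071
chr4	1100000	1110000	G00072
chr4	1200000	1210000	G00073
chr4	1300000	1310000	G00074
chr4	1400000	1410000	G00075
chr4	1500000	1510000	G00076
chr4	1600000	1610000	G00077
chr4	1700000	1710000	G00078
chr4	1800000	1810000	G00079
chr4	1900000	1910000	G00080
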