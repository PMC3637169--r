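sample	chromosome	start	end	value
S001	chr3	1400001	1710000	0
S001	chr3	1400001	1910000	3
S001	chr2	100001	310000	1
S001	chr2	1700001	1910000	3
S001	chr4	1100001	1310000	3
S002	chr1	1300001	1610000	1
S002	chr2	500001	1510000	0
S002	chr4	200001	210000	4
S003	chr2	1200001	1910000	4
S003	chr2	1600001	1710000	0
S003	chr4	100001	910000	3
S003	chr2	1	710000	3
S003	chr1	600001	1110000	3
S003	chr2	1	410000	1
S003	chr2	1900001	1910000	4
S004	chr3	800001	1710000	3
S004	chr4	500001	810000	3
S004	chr3	1500001	1610000	3
S004	chr1	700001	910000	4
S004	chr2	1900001	1910000	3
S005	chr3	1000001	1310000	0
S005	chr2	1500001	1910000	3
S005	chr4	700001	1110000	3
S006	chr1	800001	1010000	0
S006	chr3	600001	1110000	1
S006	chr1	1200001	1310000	1
S006	chr4	300001	510000	3
S006	chr4	700001	1310000	0
S006	chr2	1900001	1910000	3
S006	chr3	1500001	1510000	1
S007	chr2	1600001	1810000	1
S007	chr4	1300001	1910000	3
S007	chr2	1300001	1910000	1
S008	chr4	1400001	1410000	3
S008	chr4	200001	1210000	3
S008	chr3	600001	910000	3
S008	chr4	1600001	1910000	0
S008	chr4	1100001	1310000	1
S008	chr2	1600001	1910000	3
S008	chr3	1900001	1910000	1
S008	chr2	200001	310000	1
S008	chr2	1900001	1910000	3
S008	chr3	1200001	1510000	0
S008	chr4	1100001	1110000	3
S009	chr3	1800001	1910000	3
S009	chr1	1800001	1910000	3
S009	chr3	1500001	1910000	1
S009	chr1	1900001	1910000	1
S009	chr1	100001	1110000	3
S009	chr1	1200001	1710000	0
S009	chr1	600001	1910000	3
S009	chr2	900001	910000	4
S009	chr4	1000001	1310000	1
S009	chr2	1800001	1910000	4
S009	chr4	1100001	1310000	3
S010	chr2	1400001	1410000	1
S010	chr4	500001	1810000	1
S010	chr4	800001	1010000	3
S010	chr1	700001	710000	3
S010	chr2	300001	410000	1
S010	chr4	1000001	1110000	4
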