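sample	gene
S001	G00033
S002	G00040
S002	G00056
S003	G00040
S004	G00004
S004	G00008
S004	G00040
S004	G00070
S004	G00072
S005	G00021
S005	G00032
S005	G00040
S005	G00061
S005	G00073
S006	G00003
S006	G00008
S006	G00030
S006	G00065
S007	G00002
S007	G00008
S007	G00024
S007	G00051
S008	G00002
S008	G00004
S008	G00049
S008	G00072
S009	G00007
S009	G00024
S009	G00051
S009	G00072
S010	G00007
S010	G00008
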