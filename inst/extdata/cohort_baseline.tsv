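study	n	n_female	n_european_american	n_latino	n_african_american	n_ar	n_asthma
CHS	2881	1344	1552	1329	0	1096	1206
CAMP	384	142	384	0	0	199	384
CAG/CSGA/SARP	283	150	98	0	185	245	283
GALA1	521	230	0	521	0	434	521
MCCAS	476	198	0	476	0	250	476
GRAAD	809	474	0	0	809	377	228
SAPPHIRE	279	219	0	0	279	111	148
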