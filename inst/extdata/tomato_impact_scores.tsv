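gene	label	provean	sift4g	ppved
g6365.t1	P63A	-7.68	0.01	0.82
g9938.t1	R79W	-3.50	0.00	0.04
g9938.t1	H398Q	-7.31	0.37	0.29
g9938.t1	Y417C	-8.43	0.00	0.51
g18960.t1	S570P	-4.75	0.00	0.90
g18960.t1	A523P	-3.00	0.41	0.02
g29005.t1	D75G	-3.98	0.12	0.07
g29005.t1	K305R	-2.69	0.17	0.76
g29005.t1	P36L	-4.87	0.02	0.56
g14532.t1	Q178L	-5.54	0.03	0.26
g14532.t1	S450C	-4.32	0.01	0.36
g14532.t1	H544Q	-2.54	0.34	0.01
g14532.t1	R1194H	-3.93	0.02	0.85
g14972.t1	S41Y	-2.67	0.02	0.03
g14972.t1	R44P	-2.79	0.06	0.07
g14972.t1	A48D	-4.78	0.01	0.68
g27963.t1	F271L	-5.43	0.08	0.04
g27963.t1	K295E	-3.70	0.01	0.79
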