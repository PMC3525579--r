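population	latitude	longitude	year
MAL	36.717	-4.421	2008
VAL	39.533	-0.375	2008
RAS	40.95	0.596	2008
BCN	41.417	2.169	2007
MON	43.583	3.877	2009
DIJ	47.3	5.042	2009
GRO	53.217	6.567	2009
DRO	59.567	10.63	2005
SUN	60.133	13.133	2005
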