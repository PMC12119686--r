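subject_id	group	e36_38	e62_66	e80_83	e99_101	e117_123	e134_137	e141_152	e155_158	e168_170	e192_196	e199_206
SLE01	SLE	1	0	1	1	0	1	0	1	1	1	0
SLE02	SLE	0	1	1	1	0	1	0	1	1	1	0
SLE03	SLE	1	0	1	1	0	1	1	0	1	1	0
SLE04	SLE	0	0	1	1	0	1	0	1	1	0	1
SLE05	SLE	0	0	1	1	0	1	1	0	1	1	0
SLE06	SLE	0	0	1	1	0	1	0	1	1	0	0
SLE07	SLE	0	0	1	0	0	1	1	0	1	0	0
SLE08	SLE	0	0	1	0	0	0	0	1	1	0	1
SLE09	SLE	0	0	1	0	0	0	1	0	1	0	0
SLE10	SLE	0	1	0	0	0	0	0	1	1	0	0
SLE11	SLE	0	0	1	0	0	0	1	0	1	0	0
SLE12	SLE	0	0	0	0	0	0	0	1	1	0	0
SLE13	SLE	0	0	0	1	0	0	1	0	0	0	0
SLE14	SLE	0	0	0	0	1	0	0	1	0	0	0
SLE15	SLE	0	0	0	0	0	1	1	0	0	0	0
SLE16	SLE	0	0	0	0	0	0	0	1	1	0	0
SLE17	SLE	0	0	0	0	0	0	1	0	0	0	0
SLE18	SLE	0	0	0	0	0	0	0	1	0	0	0
SLE19	SLE	0	0	0	0	0	0	1	0	0	0	0
SLE20	SLE	0	0	0	0	0	0	0	1	0	0	0
SLE21	SLE	0	0	0	0	0	0	1	0	0	0	0
SLE22	SLE	0	0	0	0	0	0	0	1	0	0	0
SLE23	SLE	0	0	0	0	0	0	0	0	0	1	0
SLE24	SLE	0	0	0	0	0	0	0	0	0	0	1
SLE25	SLE	0	0	0	0	0	0	0	0	0	0	0
SLE26	SLE	0	0	0	0	0	0	0	0	0	0	0
SLE27	SLE	0	0	0	0	0	0	0	0	0	0	0
SLE28	SLE	0	0	0	0	0	0	0	0	0	0	0
SLE29	SLE	0	0	0	0	0	0	0	0	0	0	0
SLE30	SLE	0	0	0	0	0	0	0	0	0	0	0
SLE31	SLE	0	0	0	0	0	0	0	0	0	0	0
SLE32	SLE	0	0	0	0	0	0	0	0	0	0	0
SLE33	SLE	0	0	0	0	0	0	0	0	0	0	0
SLE34	SLE	0	0	0	0	0	0	0	0	0	0	0
SLE35	SLE	0	0	0	0	0	0	0	0	0	0	0
SLE36	SLE	0	0	0	0	0	0	0	0	0	0	0
SLE37	SLE	0	0	0	0	0	0	0	0	0	0	0
SLE38	SLE	0	0	0	0	0	0	0	0	0	0	0
SLE39	SLE	0	0	0	0	0	0	0	0	0	0	0
SLE40	SLE	0	0	0	0	0	0	0	0	0	0	0
SLE41	SLE	0	0	0	0	0	0	0	0	0	0	0
SLE42	SLE	0	0	0	0	0	0	0	0	0	0	0
HBD01	HBD	0	0	1	0	1	0	0	1	1	0	0
HBD02	HBD	0	0	0	0	1	0	0	0	1	0	0
HBD03	HBD	0	0	0	0	0	0	1	0	0	0	0
HBD04	HBD	0	0	0	0	0	1	0	0	0	0	0
HBD05	HBD	0	0	0	0	0	0	0	0	0	0	0
HBD06	HBD	0	0	0	0	0	0	0	0	0	0	0
HBD07	HBD	0	0	0	0	0	0	0	0	0	0	0
HBD08	HBD	0	0	0	0	0	0	0	0	0	0	0
HBD09	HBD	0	0	0	0	0	0	0	0	0	0	0
HBD10	HBD	0	0	0	0	0	0	0	0	0	0	0
HBD11	HBD	0	0	0	0	0	0	0	0	0	0	0
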