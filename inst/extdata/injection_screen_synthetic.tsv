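region_id	n_alive	n_lens	n_specific
REG001	104	52	36
REG002	97	45	31
REG003	110	61	40
REG004	88	40	27
REG005	102	55	33
REG006	95	48	35
REG007	118	66	41
REG008	91	42	29
REG009	106	58	38
REG010	99	51	30
REG011	84	39	26
REG012	113	63	42
REG013	93	47	32
REG014	108	57	37
REG015	86	41	28
REG016	101	54	34
REG017	96	44	30
REG018	115	64	43
REG019	90	43	27
REG020	100	50	4
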