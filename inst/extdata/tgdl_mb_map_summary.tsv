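# Published characteristics of the hazelnut TGdL (female) and MB (male)
# framework linkage maps: per-group size (cM), marker count, marker
# density (cM/interval) and number of gaps > 5 cM.
map	group	size_cm	n_markers	density	gaps
TGdL	TGdL_01	99.1	205	0.5	1
TGdL	TGdL_02	103.2	166	0.6	2
TGdL	TGdL_03	65.1	83	0.8	0
TGdL	TGdL_04	78.1	128	0.6	0
TGdL	TGdL_05	84.0	108	0.8	1
TGdL	TGdL_06	80.2	69	1.2	1
TGdL	TGdL_07	69.8	124	0.6	0
TGdL	TGdL_08	72.7	76	1.0	1
TGdL	TGdL_09a	50.1	47	1.1	0
TGdL	TGdL_09b	41.9	54	0.8	0
TGdL	TGdL_10a	22.1	29	0.8	0
TGdL	TGdL_10b	56.9	45	1.3	1
TGdL	TGdL_11	77.2	102	0.8	1
MB	MB_01	113.5	172	0.7	0
MB	MB_02	119.2	156	0.8	0
MB	MB_03	83.5	79	1.1	1
MB	MB_04	79.5	144	0.6	0
MB	MB_05	80.9	115	0.7	0
MB	MB_06	50.6	39	1.3	2
MB	MB_07	64.5	107	0.6	0
MB	MB_08	65.0	67	1.0	0
MB	MB_09	90.8	148	0.6	1
MB	MB_10	74.9	78	1.0	1
MB	MB_11	76.7	106	0.7	0
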