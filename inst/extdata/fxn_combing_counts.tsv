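sample	group	total_molecules	replicating_molecules	total_forks	unidirectional_n	paused_n	asynchronous_n	central_origins	central_origin_molecules
GM15851	control	61	39	122	23	26	8	20	18
H691	control	124	80	203	53	29	6	20	16
GM15850	frda	124	70	151	49	21	11	19	14
GM16227	frda	63	42	101	26	18	1	17	11
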