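sample	fraction	pattern	substage	n
control	S1	SS	early	193
control	S1	SS	mid	8
control	S1	SS	late	0
control	S1	DD	early	0
control	S1	DD	mid	24
control	S1	DD	late	8
control	S1	SD	early	111
control	S1	SD	mid	138
control	S1	SD	late	0
control	S1	OTHER	early	11
control	S1	OTHER	mid	14
control	S1	OTHER	late	0
control	S2	SS	early	105
control	S2	SS	mid	10
control	S2	SS	late	0
control	S2	DD	early	2
control	S2	DD	mid	67
control	S2	DD	late	21
control	S2	SD	early	108
control	S2	SD	mid	166
control	S2	SD	late	5
control	S2	OTHER	early	7
control	S2	OTHER	mid	16
control	S2	OTHER	late	0
control	S3	SS	early	20
control	S3	SS	mid	10
control	S3	SS	late	0
control	S3	DD	early	1
control	S3	DD	mid	142
control	S3	DD	late	36
control	S3	SD	early	55
control	S3	SD	mid	205
control	S3	SD	late	4
control	S3	OTHER	early	5
control	S3	OTHER	mid	14
control	S3	OTHER	late	0
control	S4	SS	early	4
control	S4	SS	mid	7
control	S4	SS	late	0
control	S4	DD	early	1
control	S4	DD	mid	182
control	S4	DD	late	80
control	S4	SD	early	11
control	S4	SD	mid	133
control	S4	SD	late	5
control	S4	OTHER	early	1
control	S4	OTHER	mid	11
control	S4	OTHER	late	1
frda	S1	SS	early	251
frda	S1	SS	mid	19
frda	S1	SS	late	0
frda	S1	DD	early	0
frda	S1	DD	mid	10
frda	S1	DD	late	3
frda	S1	SD	early	119
frda	S1	SD	mid	80
frda	S1	SD	late	2
frda	S1	OTHER	early	34
frda	S1	OTHER	mid	28
frda	S1	OTHER	late	0
frda	S2	SS	early	178
frda	S2	SS	mid	15
frda	S2	SS	late	0
frda	S2	DD	early	2
frda	S2	DD	mid	26
frda	S2	DD	late	6
frda	S2	SD	early	102
frda	S2	SD	mid	116
frda	S2	SD	late	3
frda	S2	OTHER	early	39
frda	S2	OTHER	mid	16
frda	S2	OTHER	late	1
frda	S3	SS	early	19
frda	S3	SS	mid	9
frda	S3	SS	late	0
frda	S3	DD	early	1
frda	S3	DD	mid	100
frda	S3	DD	late	103
frda	S3	SD	early	5
frda	S3	SD	mid	192
frda	S3	SD	late	34
frda	S3	OTHER	early	3
frda	S3	OTHER	mid	21
frda	S3	OTHER	late	12
frda	S4	SS	early	3
frda	S4	SS	mid	1
frda	S4	SS	late	0
frda	S4	DD	early	0
frda	S4	DD	mid	65
frda	S4	DD	late	244
frda	S4	SD	early	1
frda	S4	SD	mid	70
frda	S4	SD	late	31
frda	S4	OTHER	early	0
frda	S4	OTHER	mid	11
frda	S4	OTHER	late	18
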