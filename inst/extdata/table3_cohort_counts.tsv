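arm	n	CR	PR	SD	PD	male	stage_I	stage_II	stage_IIIa	stage_IV	ps0	ps1	ps2	xelox	antihypertensive
non_PPI	42	0	21	17	4	21	1	1	5	35	21	21	0	21	7
PPI	16	0	4	7	5	10	0	0	1	15	8	7	1	12	3
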