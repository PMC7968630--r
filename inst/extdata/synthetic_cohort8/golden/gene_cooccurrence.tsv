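gene	ASXL1	CD274	CD276	DNMT3A	EZH2	IDH1	RUNX1	SF3B1	TET2
ASXL1	3	3	3	0	1	0	3	0	0
CD274	3	3	3	0	1	0	3	0	0
CD276	3	3	3	0	1	0	3	0	0
DNMT3A	0	0	0	5	1	5	0	5	5
EZH2	1	1	1	1	2	1	1	1	1
IDH1	0	0	0	5	1	5	0	5	5
RUNX1	3	3	3	0	1	0	3	0	0
SF3B1	0	0	0	5	1	5	0	5	5
TET2	0	0	0	5	1	5	0	5	5
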