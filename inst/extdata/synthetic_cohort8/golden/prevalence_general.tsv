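gene	n_mutated	fraction	percent
ASXL1	3	37.5	38
CD274	3	37.5	38
CD276	3	37.5	38
DNMT3A	4	50	50
EZH2	2	25	25
IDH1	1	12.5	12
RUNX1	3	37.5	38
SF3B1	2	25	25
TET2	2	25	25
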