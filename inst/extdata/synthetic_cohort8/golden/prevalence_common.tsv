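gene	n_mutated	fraction	percent
ASXL1	3	37.5	38
CD274	3	37.5	38
CD276	3	37.5	38
DNMT3A	5	62.5	62
EZH2	2	25	25
IDH1	6	75	75
RUNX1	3	37.5	38
SF3B1	5	62.5	62
TET2	5	62.5	62
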