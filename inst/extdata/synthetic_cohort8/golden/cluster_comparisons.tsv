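field	type	statistic	p	p_adjusted
age	mann_whitney	12	0.25	0.916666666666667
blasts_pct	mann_whitney	4	0.392857142857143	0.916666666666667
hemoglobin	mann_whitney	9	0.785714285714286	0.916666666666667
neutrophils	mann_whitney	6	0.785714285714286	0.916666666666667
platelets	mann_whitney	5	0.571428571428571	0.916666666666667
ipssr_numeric	mann_whitney	3.5	0.339285714285714	0.916666666666667
hsct	fisher	0.75	1	1
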