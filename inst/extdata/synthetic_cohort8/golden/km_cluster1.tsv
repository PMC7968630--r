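time	n_risk	n_event	surv	se	lower	upper
4.534	5	1	0.8	0.178885438199983	0.203809263267639	0.969179788866743
66.939	3	1	0.533333333333333	0.24825315633367	0.0683320878472029	0.863071182738792
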