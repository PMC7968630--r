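time	n_risk	n_event	surv	se	lower	upper
15.669	2	1	0.5	0.353553390593274	0.00598308763914575	0.910410084836737
53.788	1	1	0	NA	NA	NA
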