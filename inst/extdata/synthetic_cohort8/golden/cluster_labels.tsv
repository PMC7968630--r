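patient_id	cluster
P001	1
P002	1
P003	2
P004	2
P005	1
P006	1
P007	2
P008	1
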