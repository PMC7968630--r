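patient_id	n_variants	per_mb
P001	3	39.2223515107142
P002	1	13.0741171702381
P003	6	78.4447030214285
P004	9	117.667054532143
P005	2	26.1482343404762
P006	1	13.0741171702381
P007	7	91.5188201916666
P008	2	26.1482343404762
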