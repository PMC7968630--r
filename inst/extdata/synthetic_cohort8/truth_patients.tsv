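patient_id	true_cluster	true_time
P001	1	617.110940352357
P002	1	4.53423190265908
P003	2	15.6685541832831
P004	2	53.9298558758843
P005	1	130.102943567544
P006	1	66.9394536790523
P007	2	53.7880650376737
P008	1	143.49133930543
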