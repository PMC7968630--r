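patient_id	age	ipssr_category	ipssr_numeric	blasts_pct	hemoglobin	neutrophils	platelets	hsct	followup_time	event
P001	44	high	3	0.2	109	0.39	274	FALSE	99.842	FALSE
P002	72	high	3	2.1	80	1.56	98	TRUE	4.534	TRUE
P003	42	high	3	17.6	86	0.91	119	FALSE	15.669	TRUE
P004	51	very_high	4	15.6	85	0.75	122	TRUE	12.578	FALSE
P005	50	high	3	16.7	108	1.85	76	TRUE	82.516	FALSE
P006	53	intermediate	2	6.8	84	0.6	66	FALSE	66.939	TRUE
P007	33	very_high	4	5.6	57	0.79	67	TRUE	53.788	TRUE
P008	43	very_high	4	8.3	76	0.12	62	TRUE	34.295	FALSE
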