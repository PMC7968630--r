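variant	P001	P002	P003	P004	P005	P006	P007	P008
chr1:1001085:C:G	0	0	25.600000000000001	36.100000000000001	0	0	22.399999999999999	0
chr1:1001381:C:G	0	0	31.600000000000001	16.100000000000001	0	0	0	0
chr10:1001159:T:A	0	0	0	29.199999999999999	0	0	37.799999999999997	0
chr10:1001455:T:A	0	0	15.300000000000001	17.600000000000001	0	0	31.5	0
chr11:1001196:A:C	0	0	20.600000000000001	22.399999999999999	0	0	12.4	0
chr11:1001492:A:C	0	0	17	40.5	0	0	26.100000000000001	0
chr13:1001048:A:C	47.5	27.5	0	0	19.699999999999999	35	0	23.399999999999999
chr13:1001344:A:C	33.799999999999997	0	0	0	6.2000000000000002	16.899999999999999	0	8.0999999999999996
chr15:1000359:T:A	47.200000000000003	0	0	47.700000000000003	0	0	0	0
chr16:1001011:T:A	19.399999999999999	48.5	0	0	49.600000000000001	14.1	0	12.9
chr16:1001307:T:A	25.300000000000001	16.100000000000001	0	0	25.5	7.5	0	13.800000000000001
chr5:1001418:G:T	0	0	42	9.8000000000000007	0	0	9.6999999999999993	0
chr6:1000937:C:G	36.399999999999999	17	0	0	0	0	0	0
chr6:1001233:C:G	5.0999999999999996	21.100000000000001	0	0	19	20	0	43.799999999999997
chr8:1000974:G:T	0	0	0	0	18.699999999999999	0	0	12.199999999999999
chr8:1001270:G:T	15.9	8.6999999999999993	0	0	19.399999999999999	44.899999999999999	0	36.399999999999999
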