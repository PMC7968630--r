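chr1	1000000	1002497
chr10	1000000	1005970
chr11	1000000	1006967
chr12	1000000	1002464
chr13	1000000	1003461
chr14	1000000	1004458
chr15	1000000	1005455
chr16	1000000	1006452
chr17	1000000	1001949
chr18	1000000	1002946
chr2	1000000	1003494
chr3	1000000	1004491
chr4	1000000	1005488
chr5	1000000	1006485
chr6	1000000	1001982
chr7	1000000	1002979
chr8	1000000	1003976
chr9	1000000	1004973
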