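variant	anchor
chr1:1001085:C:G	0
chr1:1001381:C:G	0
chr10:1001159:T:A	0
chr10:1001455:T:A	0
chr11:1001196:A:C	0
chr11:1001492:A:C	0
chr13:1001048:A:C	0
chr13:1001344:A:C	0
chr15:1000359:T:A	0
chr16:1001011:T:A	0
chr16:1001307:T:A	0
chr5:1001418:G:T	0
chr6:1000937:C:G	0
chr6:1001233:C:G	0
chr8:1000974:G:T	0
chr8:1001270:G:T	0
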