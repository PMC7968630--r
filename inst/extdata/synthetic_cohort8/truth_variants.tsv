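variant	gene	origin	alt_freq
chr1:1000137:C:G	ASXL1	germline	0.05
chr10:1000174:G:T	CD274	germline	0.05
chr11:1000211:T:A	CD276	germline	0.05
chr12:1000248:A:C	DICER1	germline	0.05
chr13:1000285:C:G	DNMT3A	germline	0.05
chr14:1000322:G:T	DROSHA	germline	0.05
chr15:1000359:T:A	EZH2	germline	0.05
chr16:1000396:A:C	IDH1	germline	0.05
chr17:1000433:C:G	IDH2	germline	0.05
chr18:1000470:G:T	LAG3	germline	0.05
chr2:1000507:T:A	MFSD11	germline	0.05
chr3:1000544:A:C	PDCD1	germline	0.05
chr6:1000937:C:G	SF3B1	somatic	NA
chr8:1000974:G:T	TET2	somatic	NA
chr16:1001011:T:A	IDH1	somatic	NA
chr13:1001048:A:C	DNMT3A	somatic	NA
chr1:1001085:C:G	ASXL1	somatic	NA
chr5:1001122:G:T	RUNX1	somatic	NA
chr10:1001159:T:A	CD274	somatic	NA
chr11:1001196:A:C	CD276	somatic	NA
chr6:1001233:C:G	SF3B1	somatic	NA
chr8:1001270:G:T	TET2	somatic	NA
chr16:1001307:T:A	IDH1	somatic	NA
chr13:1001344:A:C	DNMT3A	somatic	NA
chr1:1001381:C:G	ASXL1	somatic	NA
chr5:1001418:G:T	RUNX1	somatic	NA
chr10:1001455:T:A	CD274	somatic	NA
chr11:1001492:A:C	CD276	somatic	NA
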