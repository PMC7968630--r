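variant	statistic	p	p_adjusted
chr10:1001455:T:A	0	0.0178571428571429	0.0571428571428571
chr11:1001196:A:C	0	0.0178571428571429	0.0571428571428571
chr11:1001492:A:C	0	0.0178571428571429	0.0571428571428571
chr1:1001085:C:G	0	0.0178571428571429	0.0571428571428571
chr5:1001418:G:T	0	0.0178571428571429	0.0571428571428571
chr13:1001048:A:C	15	0.0357142857142857	0.0571428571428571
chr16:1001011:T:A	15	0.0357142857142857	0.0571428571428571
chr16:1001307:T:A	15	0.0357142857142857	0.0571428571428571
chr6:1001233:C:G	15	0.0357142857142857	0.0571428571428571
chr8:1001270:G:T	15	0.0357142857142857	0.0571428571428571
chr10:1001159:T:A	2.5	0.107142857142857	0.131868131868132
chr13:1001344:A:C	13.5	0.107142857142857	0.131868131868132
chr1:1001381:C:G	2.5	0.107142857142857	0.131868131868132
chr6:1000937:C:G	10.5	0.464285714285714	0.495238095238095
chr8:1000974:G:T	10.5	0.464285714285714	0.495238095238095
chr15:1000359:T:A	6	0.732142857142857	0.732142857142857
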