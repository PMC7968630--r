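patient_id	sample_time	chrom	pos	ref	alt	gene	consequence	ref_depth	alt_depth	vaf	pop_af	cosmic_flag	clinvar_flag
P001	0	chr10	1000174	G	T	CD274	intronic	483	517	51.700000000000003	NA	absent	FALSE
P001	0	chr13	1001048	A	C	DNMT3A	nonsense	525	475	47.5	NA	present	FALSE
P001	0	chr13	1001344	A	C	DNMT3A	frameshift	662	338	33.799999999999997	NA	absent	FALSE
P001	0	chr15	1000359	T	A	EZH2	missense	528	472	47.200000000000003	NA	absent	FALSE
P001	0	chr16	1001011	T	A	IDH1	missense	806	194	19.399999999999999	NA	heme_associated	FALSE
P001	0	chr16	1001307	T	A	IDH1	missense	747	253	25.300000000000001	NA	present	FALSE
P001	0	chr6	1000937	C	G	SF3B1	missense	636	364	36.399999999999999	NA	present	FALSE
P001	0	chr6	1001233	C	G	SF3B1	missense	949	51	5.0999999999999996	NA	present	FALSE
P001	0	chr8	1001270	G	T	TET2	frameshift	841	159	15.9	NA	absent	FALSE
P002	0	chr1	1000137	C	G	ASXL1	intronic	468	532	53.200000000000003	NA	absent	FALSE
P002	0	chr13	1001048	A	C	DNMT3A	nonsense	725	275	27.5	NA	present	FALSE
P002	0	chr16	1001011	T	A	IDH1	missense	515	485	48.5	NA	heme_associated	FALSE
P002	0	chr16	1001307	T	A	IDH1	missense	839	161	16.100000000000001	NA	present	FALSE
P002	0	chr2	1000507	T	A	MFSD11	intronic	499	501	50.100000000000001	NA	absent	FALSE
P002	0	chr6	1000937	C	G	SF3B1	missense	830	170	17	NA	present	FALSE
P002	0	chr6	1001233	C	G	SF3B1	missense	789	211	21.100000000000001	NA	present	FALSE
P002	0	chr8	1001270	G	T	TET2	frameshift	913	87	8.6999999999999993	NA	absent	FALSE
P003	0	chr1	1001085	C	G	ASXL1	missense	744	256	25.600000000000001	NA	heme_associated	FALSE
P003	0	chr1	1001381	C	G	ASXL1	missense	684	316	31.600000000000001	NA	present	FALSE
P003	0	chr10	1001455	T	A	CD274	missense	847	153	15.300000000000001	NA	present	FALSE
P003	0	chr11	1001196	A	C	CD276	missense	794	206	20.600000000000001	NA	absent	FALSE
P003	0	chr11	1001492	A	C	CD276	missense	830	170	17	NA	absent	FALSE
P003	0	chr5	1001418	G	T	RUNX1	missense	580	420	42	NA	absent	FALSE
P004	0	chr1	1001085	C	G	ASXL1	missense	639	361	36.100000000000001	NA	heme_associated	FALSE
P004	0	chr1	1001381	C	G	ASXL1	missense	839	161	16.100000000000001	NA	present	FALSE
P004	0	chr10	1001159	T	A	CD274	missense	708	292	29.199999999999999	NA	absent	FALSE
P004	0	chr10	1001455	T	A	CD274	missense	824	176	17.600000000000001	NA	present	FALSE
P004	0	chr11	1001196	A	C	CD276	missense	776	224	22.399999999999999	NA	absent	FALSE
P004	0	chr11	1001492	A	C	CD276	missense	595	405	40.5	NA	absent	FALSE
P004	0	chr15	1000359	T	A	EZH2	missense	523	477	47.700000000000003	NA	absent	FALSE
P004	0	chr5	1001122	G	T	RUNX1	missense	605	395	39.5	NA	heme_associated	FALSE
P004	0	chr5	1001418	G	T	RUNX1	missense	902	98	9.8000000000000007	NA	absent	FALSE
P005	0	chr13	1001048	A	C	DNMT3A	nonsense	803	197	19.699999999999999	NA	present	FALSE
P005	0	chr13	1001344	A	C	DNMT3A	frameshift	938	62	6.2000000000000002	NA	absent	FALSE
P005	0	chr16	1001011	T	A	IDH1	missense	504	496	49.600000000000001	NA	heme_associated	FALSE
P005	0	chr16	1001307	T	A	IDH1	missense	745	255	25.5	NA	present	FALSE
P005	0	chr17	1000433	C	G	IDH2	synonymous	492	508	50.799999999999997	NA	absent	FALSE
P005	0	chr6	1001233	C	G	SF3B1	missense	810	190	19	NA	present	FALSE
P005	0	chr8	1000974	G	T	TET2	frameshift	813	187	18.699999999999999	NA	heme_associated	FALSE
P005	0	chr8	1001270	G	T	TET2	frameshift	806	194	19.399999999999999	NA	absent	FALSE
P006	0	chr13	1001048	A	C	DNMT3A	nonsense	650	350	35	NA	present	FALSE
P006	0	chr13	1001344	A	C	DNMT3A	frameshift	831	169	16.899999999999999	NA	absent	FALSE
P006	0	chr16	1001011	T	A	IDH1	missense	859	141	14.1	NA	heme_associated	FALSE
P006	0	chr16	1001307	T	A	IDH1	missense	925	75	7.5	NA	present	FALSE
P006	0	chr6	1001233	C	G	SF3B1	missense	800	200	20	NA	present	FALSE
P006	0	chr8	1001270	G	T	TET2	frameshift	551	449	44.899999999999999	NA	absent	FALSE
P007	0	chr1	1001085	C	G	ASXL1	missense	776	224	22.399999999999999	NA	heme_associated	FALSE
P007	0	chr10	1000174	G	T	CD274	intronic	484	516	51.600000000000001	NA	absent	FALSE
P007	0	chr10	1001159	T	A	CD274	missense	622	378	37.799999999999997	NA	absent	FALSE
P007	0	chr10	1001455	T	A	CD274	missense	685	315	31.5	NA	present	FALSE
P007	0	chr11	1001196	A	C	CD276	missense	876	124	12.4	NA	absent	FALSE
P007	0	chr11	1001492	A	C	CD276	missense	739	261	26.100000000000001	NA	absent	FALSE
P007	0	chr16	1000396	A	C	IDH1	missense	501	499	49.899999999999999	NA	absent	FALSE
P007	0	chr2	1000507	T	A	MFSD11	intronic	488	512	51.200000000000003	NA	absent	FALSE
P007	0	chr5	1001418	G	T	RUNX1	missense	903	97	9.6999999999999993	NA	absent	FALSE
P008	0	chr13	1001048	A	C	DNMT3A	nonsense	766	234	23.399999999999999	NA	present	FALSE
P008	0	chr13	1001344	A	C	DNMT3A	frameshift	919	81	8.0999999999999996	NA	absent	FALSE
P008	0	chr16	1001011	T	A	IDH1	missense	871	129	12.9	NA	heme_associated	FALSE
P008	0	chr16	1001307	T	A	IDH1	missense	862	138	13.800000000000001	NA	present	FALSE
P008	0	chr6	1001233	C	G	SF3B1	missense	562	438	43.799999999999997	NA	present	FALSE
P008	0	chr8	1000974	G	T	TET2	frameshift	878	122	12.199999999999999	NA	heme_associated	FALSE
P008	0	chr8	1001270	G	T	TET2	frameshift	636	364	36.399999999999999	NA	absent	FALSE
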