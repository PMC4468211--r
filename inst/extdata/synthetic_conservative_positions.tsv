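chrom	pos	kind	tier	gene
chr1	1000633	SNV	conservative	GENE01
chr1	1001097	SNV	conservative	GENE01
chr1	1001251	SNV	conservative	GENE01
chr1	1002096	SNV	conservative	GENE01
chr1	1002368	SNV	conservative	GENE01
chr1	1002608	SNV	conservative	GENE01
chr1	1004068	indel	conservative	GENE01
chr2	2000355	SNV	conservative	GENE02
chr2	2001902	SNV	conservative	GENE02
chr2	2003910	SNV	conservative	GENE02
chr2	2003953	SNV	conservative	GENE02
chr2	2004260	SNV	conservative	GENE02
chr3	3000898	SNV	conservative	GENE03
chr3	3000931	SNV	conservative	GENE03
chr3	3000996	SNV	conservative	GENE03
chr3	3002014	SNV	conservative	GENE03
chr3	3004696	indel	conservative	GENE03
chr3	3004716	indel	conservative	GENE03
chr4	4000258	SNV	conservative	GENE04
chr4	4000480	SNV	conservative	GENE04
chr4	4000859	SNV	conservative	GENE04
chr4	4002071	SNV	conservative	GENE04
chr4	4003943	SNV	conservative	GENE04
chr4	4004001	indel	conservative	GENE04
chr1	5000298	SNV	conservative	GENE05
chr1	5002453	SNV	conservative	GENE05
chr1	5003982	SNV	conservative	GENE05
chr2	6000835	SNV	conservative	GENE06
chr2	6000981	SNV	conservative	GENE06
chr2	6001539	SNV	conservative	GENE06
chr2	6002273	SNV	conservative	GENE06
chr2	6002551	SNV	conservative	GENE06
chr2	6003426	SNV	conservative	GENE06
chr2	6003719	indel	conservative	GENE06
chr3	7000625	SNV	conservative	GENE07
chr3	7000726	SNV	conservative	GENE07
chr3	7000944	SNV	conservative	GENE07
chr3	7003031	SNV	conservative	GENE07
chr3	7003316	indel	conservative	GENE07
chr3	7004357	indel	conservative	GENE07
chr4	8000032	SNV	conservative	GENE08
chr4	8000516	SNV	conservative	GENE08
chr4	8001014	SNV	conservative	GENE08
chr4	8001395	SNV	conservative	GENE08
chr4	8002817	SNV	conservative	GENE08
chr4	8004225	SNV	conservative	GENE08
chr4	8004469	SNV	conservative	GENE08
chr4	8004745	indel	conservative	GENE08
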