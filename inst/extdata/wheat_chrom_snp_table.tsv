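chrom	snp_count	first_mb	last_mb
1A	686	1.145	593.790
1B	881	1.299	688.328
1D	255	0.079	493.979
2A	912	0.718	771.354
2B	1486	0.019	800.870
2D	254	8.791	649.074
3A	832	0.608	750.539
3B	1027	0.580	829.535
3D	115	24.795	615.062
4A	574	2.705	744.515
4B	378	1.056	666.052
4D	74	3.238	509.798
5A	799	1.294	709.755
5B	1084	8.072	712.941
5D	106	62.140	555.015
6A	825	0.684	617.839
6B	1227	0.196	720.805
6D	210	0.070	473.287
7A	1293	2.083	736.572
7B	1295	1.021	750.125
7D	250	2.145	635.422
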