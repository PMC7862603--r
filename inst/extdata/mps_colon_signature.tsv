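gene_id	entrez_id	direction	weight
PER3	8863	HIGH	5.100
PRSS53	339105	HIGH	4.569
KIFC3	3801	HIGH	3.328
TYRP1	7306	HIGH	2.078
BTBD16	118663	HIGH	1.337
CHRNA3	1136	HIGH	1.047
LGR4	55366	LOW	4.597
LYAR	55646	LOW	4.439
CCT2	10576	LOW	4.404
CCNE1	898	LOW	4.226
PRMT1	3276	LOW	4.155
TESK2	10420	LOW	4.060
LYPD6	130574	LOW	3.960
F2RL1	2150	LOW	1.465
CEP55	55165	LOW	1.061
SIAE	54414	LOW	0.174
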