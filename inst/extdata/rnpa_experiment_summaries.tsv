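# Published per-experiment average growth parameters for E. coli rnpA
# heterologous-complementation lineages. Each experiment is one microplate:
# one test lineage (MTea1/pSWAP-<source>) grown alongside the within-plate
# control lineage MTea1/pSWAP-Ec carrying the native E. coli rnpA.
# mean/sd columns: mu_max in 1/h, tti in hours.
experiment	lineage	role	mean_mu_max	sd_mu_max	mean_tti	sd_tti
1	Pm	test	0.661	0.010	7.65	0.16
1	Ec	control	0.674	0.035	7.54	0.09
2	Pa	test	0.712	0.014	9.51	0.24
2	Ec	control	0.652	0.025	7.95	0.41
3	Ab	test	0.687	0.019	7.62	0.26
3	Ec	control	0.678	0.012	7.46	0.06
4	Ng	test	0.694	0.022	6.91	0.26
4	Ec	control	0.668	0.014	6.49	0.08
5	Bs	test	0.711	0.025	7.82	0.21
5	Ec	control	0.709	0.007	7.46	0.05
6	So	test	0.704	0.030	8.32	0.21
6	Ec	control	0.681	0.017	7.53	0.13
7	Sa	test	0.747	0.019	8.51	0.11
7	Ec	control	0.720	0.020	7.48	0.08
8	Tm	test	0.675	0.020	8.23	0.24
8	Ec	control	0.655	0.010	7.49	0.14
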