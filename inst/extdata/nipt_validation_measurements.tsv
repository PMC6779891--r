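track	sample_id	fetal_fraction	vaf	n_molecules	lr_printed	nipt_printed	neonate_genotype	maternal_genotype
paternal	35A	0.088	0.004	1159	1.5e+09	0/0	0/0	0/0
paternal	07B	0.272	0.009	482	5.9e+15	0/0	0/0	0/0
paternal	38C	0.081	0.033	572	2.1e-09	0/1	0/1	0/0
paternal	49E	0.174	0.961	436	2.0e-08	0/1	0/1	1/1
paternal	38B	0.228	0.998	871	4.3e+27	1/1	1/1	1/1
paternal	52E	0.128	0.998	248	4.7e+04	1/1	1/1	1/1
paternal	17D	0.172	0.998	585	1.6e+13	1/1	1/1	1/1
paternal	18C	0.123	0.998	636	3.6e+09	1/1	1/1	1/1
paternal	52F	0.213	0.998	447	5.2e+13	1/1	1/1	1/1
paternal	04B	0.045	0.998	2742	7.1e+09	1/1	1/1	1/1
paternal	36C	0.144	0.998	755	1.4e+14	1/1	1/1	1/1
paternal	02A	0.289	0.998	1497	5.1e+64	1/1	1/1	1/1
paternal	40B	0.237	0.998	988	2.7e+33	1/1	1/1	1/1
paternal	37A	0.209	1.000	2900	1.4e+84	1/1	1/1	1/1
recessive	30B	0.153	0.477	8616	1.0e-44	normal	0/0	0/1
recessive	31B	0.171	0.478	304	1.5e-02	normal	0/0	0/1
recessive	08A	0.134	0.478	2092	3.5e-09	normal	0/0	0/1
recessive	56C	0.325	0.482	663	7.2e-12	normal	0/1	0/1
recessive	39A	0.079	0.498	1868	2.3e-02	normal	0/1	0/1
recessive	63B	0.225	0.505	1386	2.4e-08	normal	0/1	0/1
recessive	47F	0.308	0.508	1319	6.2e-14	normal	0/1	0/1
recessive	09B	0.208	0.521	1601	1.3e-04	normal	0/1	0/1
recessive	38A	0.112	0.568	2328	7.9e+07	affected	1/1	0/1
recessive	25B	0.242	0.569	360	1.7e+01	affected	1/1	0/1
recessive	40E	0.184	0.570	573	2.1e+02	affected	1/1	0/1
recessive	50C	0.179	0.586	1085	3.4e+06	affected	1/1	0/1
recessive	17B	0.219	0.603	1611	1.8e+14	affected	1/1	0/1
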