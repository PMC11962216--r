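variable	level	count_no_target	pct_no_target	count_target	pct_target	count_overall	pct_overall
sex	Female	100748	45.3	2384	46.6	103132	45.3
sex	Male	93216	41.9	2382	46.5	95598	42.0
sex	Missing	28615	12.9	355	6.9	28970	12.7
weight	< 50 kg	3996	1.8	156	3.0	4152	1.8
weight	> 100 kg	9525	4.3	247	4.8	9772	4.3
weight	50-100 kg	33330	15.0	1109	21.7	34439	15.1
weight	Missing	175728	79.0	3609	70.5	179337	78.8
age	< 18	7608	3.4	306	6.0	7914	3.5
age	> 85	2120	1.0	40	0.8	2160	0.9
age	18-64.9	89918	40.4	2759	53.9	92677	40.7
age	65-85	15172	6.8	289	5.6	15461	6.8
age	Missing	107761	48.4	1727	33.7	109488	48.1
reporter	CN	76147	34.2	1558	30.4	77705	34.1
reporter	HP	13629	6.1	210	4.1	13839	6.1
reporter	LW	5299	2.4	71	1.4	5370	2.4
reporter	MD	62367	28.0	1699	33.2	64066	28.1
reporter	OT	31675	14.2	776	15.2	32451	14.3
reporter	PH	19239	8.6	337	6.6	19576	8.6
reporter	RN	36	0.0	2	0.0	38	0.0
reporter	Missing	14187	6.4	468	9.1	14655	6.4
year	2019	14545	6.5	284	5.5	14829	6.5
year	2020	13303	6.0	212	4.1	13515	5.9
year	2021	12225	5.5	180	3.5	12405	5.4
year	2022	11671	5.2	172	3.4	11843	5.2
year	2023	12136	5.5	260	5.1	12396	5.4
country	France	1689	0.8	51	1.0	1740	0.8
country	Germany	1842	0.8	63	1.2	1905	0.8
country	Japan	6527	2.9	219	4.3	6746	3.0
country	UK	3939	1.8	158	3.1	4097	1.8
country	US	82146	36.9	1176	23.0	83322	36.6
country	Missing	6455	2.9	307	6.0	6762	3.0
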