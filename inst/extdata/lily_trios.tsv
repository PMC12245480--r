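P1	P2	P3	D-statistic	Z-score	p-value	f4-ratio	BBAA	ABBA	BABA
GYD1401	L.nan	L.lop	0.00308579	0.369102	0.712052	0.00174733	5877.3	3714.65	3691.8
L.pse	GYD1401	L.lop	0.017972	2.27389	0.0229726	0.0119824	4750	4439.19	4282.44
GYD1401	L.lop	pop1	0.0758663	9.7145	2.3e-16	0.118397	4927.49	4779.22	4105.19
GYD1401	L.lop	pop2	0.0106965	1.15728	0.247158	0.0113625	7458.7	3325.12	3254.74
L.nan	GYD1401	L.pse	0.0550863	5.93815	2.88258e-09	0.0566096	5702.08	3850.33	3448.28
GYD1401	L.nan	pop1	0.0311355	3.85562	0.000115436	0.0403276	6677.43	3846.18	3613.9
GYD1401	L.nan	pop2	0.0275163	3.69973	0.000215829	0.0252869	9268.27	2963.98	2805.23
L.pse	GYD1401	pop1	0.0429272	4.99705	5.82127e-07	0.0596947	5511.98	4380.08	4019.5
GYD1401	L.pse	pop2	0.0369419	4.77861	1.76511e-06	0.0377103	7547.91	3273.65	3040.39
pop1	GYD1401	pop2	0.00636851	0.687113	0.492012	0.00694487	6911.01	3472.72	3428.77
L.lop	L.nan	L.pse	0.00723081	1.07525	0.282265	0.00901077	4621.66	4508.23	4443.5
L.nan	L.lop	pop1	0.0525228	7.83479	4.69622e-15	0.085709	4941.36	4769.17	4293.19
L.lop	L.nan	pop2	0.00762567	1.35378	0.175806	0.00846267	7584.11	3466.44	3413.97
pop1	L.lop	L.pse	0.116581	15.7621	2.3e-16	0.122919	4887.43	4839.35	3828.81
L.lop	L.pse	pop2	0.0235523	2.95048	0.00317276	0.0246064	7083.56	3271.2	3120.65
pop1	L.lop	pop2	0.0193917	3.09725	0.00195323	0.0191996	7280.45	3204.53	3082.61
L.pse	L.nan	pop1	0.0648175	13.7787	2.3e-16	0.095082	5302.16	4781.17	4199.09
L.nan	L.pse	pop2	0.0117104	1.98558	0.0470805	0.0128124	7284.94	3381.18	3302.91
pop1	L.nan	pop2	0.0263325	4.34236	1.4096e-05	0.0299615	7299.37	3752.84	3560.26
pop1	L.pse	pop2	0.0390485	6.64054	3.12545e-11	0.0416024	6354.6	3501.86	3238.65
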