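recording_id	label	onset_s	offset_s	pitch_hz
bird01_day60	i	0.000000	0.061464	444.4513
bird01_day60	i	0.125531	0.201248	451.4628
bird01_day60	i	0.274768	0.362747	454.6604
bird01_day60	i	0.393714	0.469352	448.2806
bird01_day60	i	0.543704	0.635781	457.0359
bird01_day60	a	0.713196	0.787246	551.9553
bird01_day60	b	0.851717	0.926377	686.0640
bird01_day60	c	0.978534	1.049567	849.0261
bird01_day60	d	1.126777	1.218537	981.0781
bird01_day60	a	1.258650	1.340292	562.3806
bird01_day60	b	1.374125	1.445635	703.5310
bird01_day60	c	1.474409	1.554402	865.6086
bird01_day60	d	1.627304	1.707108	982.0280
bird01_day60	a	1.729094	1.819527	546.4311
bird01_day60	b	1.874449	1.946513	696.7228
bird01_day60	c	1.970550	2.042161	825.7196
bird01_day60	d	2.116806	2.204875	997.9069
bird01_day60	i	3.606721	3.672280	448.6196
bird01_day60	i	3.701091	3.802178	449.5247
bird01_day60	i	3.849016	3.943413	446.4425
bird01_day60	i	3.994989	4.058587	456.4139
bird01_day60	i	4.125193	4.206160	461.1886
bird01_day60	a	4.256328	4.332063	548.1353
bird01_day60	b	4.380788	4.470278	712.4841
bird01_day60	c	4.507657	4.582872	848.3254
bird01_day60	d	4.617068	4.682851	1009.6449
bird01_day60	a	4.715830	4.798092	551.4683
bird01_day60	b	4.823401	4.916535	694.0456
bird01_day60	c	4.976649	5.062527	865.9448
bird01_day60	d	5.091819	5.174519	999.6455
bird01_day60	i	6.631549	6.715319	456.2345
bird01_day60	i	6.746815	6.827454	434.3736
bird01_day60	i	6.890644	6.966767	451.6422
bird01_day60	i	6.989400	7.068203	449.4544
bird01_day60	a	7.116513	7.193779	550.6836
bird01_day60	b	7.247530	7.317974	708.4565
bird01_day60	c	7.356253	7.434460	843.1199
bird01_day60	d	7.478902	7.567516	1011.7566
bird01_day60	a	7.590952	7.676293	533.1756
bird01_day60	b	7.698824	7.787828	679.2731
bird01_day60	c	7.866851	7.951713	848.6017
bird01_day60	d	8.019938	8.112300	973.8675
bird01_day60	a	8.180812	8.263050	547.8010
bird01_day60	b	8.334333	8.429591	702.1461
bird01_day60	c	8.496659	8.575876	844.1557
bird01_day60	d	8.646449	8.725681	1026.7092
bird01_day60	i	10.044566	10.131307	457.8141
bird01_day60	i	10.179159	10.256906	449.3159
bird01_day60	i	10.304203	10.387565	457.8690
bird01_day60	i	10.433421	10.518813	445.2360
bird01_day60	i	10.556767	10.644877	452.2492
bird01_day60	i	10.674175	10.756409	458.1735
bird01_day60	i	10.784995	10.867520	454.3138
bird01_day60	a	10.889579	10.973188	554.7572
bird01_day60	b	11.010745	11.100666	699.1406
bird01_day60	c	11.174092	11.265078	861.6974
bird01_day60	d	11.314665	11.396869	1001.6837
bird01_day60	a	11.423864	11.504352	546.8395
bird01_day60	b	11.551719	11.630151	702.4629
bird01_day60	c	11.698258	11.755464	851.5876
bird01_day60	d	11.830307	11.904667	993.6491
bird01_day60	i	13.059954	13.149598	464.2025
bird01_day60	i	13.210458	13.307720	445.8062
bird01_day60	i	13.375612	13.458202	453.1138
bird01_day60	i	13.486766	13.559317	453.7931
bird01_day60	i	13.619999	13.710429	460.8238
bird01_day60	i	13.733593	13.816038	448.4300
bird01_day60	i	13.838125	13.910675	450.9907
bird01_day60	i	13.939419	14.020490	446.3870
bird01_day60	a	14.098712	14.161521	528.3506
bird01_day60	b	14.192013	14.275195	686.4102
bird01_day60	c	14.340498	14.423765	881.7426
bird01_day60	d	14.468791	14.541941	1019.3014
bird01_day60	a	14.605501	14.682322	549.0972
bird01_day60	b	14.748590	14.824871	710.6416
bird01_day60	c	14.887115	14.966986	852.4283
bird01_day60	d	15.043003	15.126393	994.4425
bird01_day60	a	15.195205	15.270208	550.9526
bird01_day60	b	15.311798	15.403685	694.1844
bird01_day60	c	15.442586	15.532364	860.6149
bird01_day60	d	15.562314	15.637116	979.2532
bird01_day60	i	16.624085	16.707994	460.0276
bird01_day60	i	16.743670	16.830367	443.9572
bird01_day60	i	16.903411	16.968086	447.7197
bird01_day60	i	17.014630	17.092738	450.6423
bird01_day60	a	17.148128	17.215854	541.5004
bird01_day60	b	17.259755	17.330008	689.7851
bird01_day60	c	17.357684	17.441040	848.1495
bird01_day60	d	17.468965	17.561978	1022.2821
bird01_day60	a	17.628042	17.708489	529.6916
bird01_day60	b	17.743091	17.822871	691.2455
bird01_day60	c	17.888153	17.977538	862.0905
bird01_day60	d	18.006417	18.087420	1014.4307
bird01_day60	a	18.134004	18.219789	541.7386
bird01_day60	b	18.285176	18.372934	705.1029
bird01_day60	c	18.413797	18.500349	853.5078
bird01_day60	d	18.542107	18.619436	977.6220
bird01_day60	i	19.861461	19.939068	449.1952
bird01_day60	i	19.993360	20.074173	446.8151
bird01_day60	i	20.151121	20.239867	450.1111
bird01_day60	i	20.281354	20.355629	451.8938
bird01_day60	i	20.411972	20.497927	452.8350
bird01_day60	i	20.537966	20.608965	444.5422
bird01_day60	a	20.638288	20.714892	544.4683
bird01_day60	b	20.784786	20.879905	707.2941
bird01_day60	c	20.935445	21.031536	857.3213
bird01_day60	d	21.097430	21.168555	1000.3670
bird01_day60	a	21.222006	21.308081	528.9349
bird01_day60	b	21.337786	21.420465	709.5171
bird01_day60	c	21.449993	21.539827	848.7158
bird01_day60	d	21.568634	21.645623	981.9212
bird01_day60	a	21.704695	21.793494	551.0333
bird01_day60	b	21.858597	21.954725	701.7803
bird01_day60	c	22.033252	22.127593	886.1548
bird01_day60	d	22.205683	22.276662	989.2767
bird01_day60	i	23.711195	23.797904	437.6017
bird01_day60	i	23.819393	23.897912	446.8119
bird01_day60	i	23.940729	24.034770	444.5861
bird01_day60	i	24.085273	24.159888	440.4058
bird01_day60	i	24.182474	24.260056	454.4815
bird01_day60	i	24.306712	24.389217	450.5361
bird01_day60	i	24.441329	24.520608	451.2477
bird01_day60	i	24.558227	24.632452	440.9481
bird01_day60	i	24.678164	24.758377	449.3280
bird01_day60	i	24.818739	24.914603	449.0112
bird01_day60	a	24.970676	25.065382	553.3040
bird01_day60	b	25.143039	25.217464	702.0042
bird01_day60	c	25.290480	25.369640	844.7403
bird01_day60	d	25.409913	25.497479	1000.6267
bird01_day60	a	25.524135	25.595382	543.2877
bird01_day60	b	25.666719	25.751775	691.6829
bird01_day60	c	25.828996	25.916141	857.3897
bird01_day60	d	25.950859	26.022235	1026.7613
bird01_day60	i	27.368400	27.441649	444.5904
bird01_day60	i	27.500360	27.579107	446.2527
bird01_day60	i	27.644382	27.705340	452.1057
bird01_day60	i	27.757625	27.837495	451.6828
bird01_day60	i	27.869361	27.962450	442.2252
bird01_day60	i	28.003074	28.090423	457.7282
bird01_day60	a	28.136598	28.219301	547.5481
bird01_day60	b	28.270689	28.346683	691.3208
bird01_day60	c	28.406154	28.494768	866.8045
bird01_day60	d	28.542370	28.623739	989.6427
bird01_day60	a	28.684851	28.741545	539.5243
bird01_day60	b	28.802022	28.894275	691.3238
bird01_day60	c	28.953207	29.037338	829.2430
bird01_day60	d	29.079100	29.170350	1015.5491
bird01_day60	i	30.447356	30.520461	455.0073
bird01_day60	i	30.559563	30.634261	466.6433
bird01_day60	i	30.684033	30.761683	449.7014
bird01_day60	i	30.793743	30.875347	459.2066
bird01_day60	a	30.916973	30.994702	553.0112
bird01_day60	b	31.024646	31.103573	704.0660
bird01_day60	c	31.171259	31.259418	866.6925
bird01_day60	d	31.313235	31.409935	960.3288
bird01_day60	a	31.453256	31.551748	538.2610
bird01_day60	b	31.599447	31.680002	717.4287
bird01_day60	c	31.719991	31.785706	819.4951
bird01_day60	d	31.817750	31.906067	1035.9350
bird01_day60	a	31.931843	32.011431	549.4646
bird01_day60	b	32.074853	32.156350	713.0637
bird01_day60	c	32.183637	32.265019	828.2324
bird01_day60	d	32.311666	32.389880	996.6369
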