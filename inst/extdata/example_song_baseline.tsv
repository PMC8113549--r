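recording_id	label	onset_s	offset_s	pitch_hz
bird01_day00	i	0.000000	0.081402	459.5937
bird01_day00	a	0.138382	0.231549	555.6386
bird01_day00	b	0.311216	0.390185	689.0920
bird01_day00	c	0.441985	0.506021	850.2000
bird01_day00	d	0.541667	0.627384	981.3519
bird01_day00	a	0.682049	0.765983	558.1828
bird01_day00	b	0.808726	0.871775	709.0716
bird01_day00	c	0.914409	1.003460	827.6233
bird01_day00	d	1.050026	1.120360	1002.2321
bird01_day00	i	2.513574	2.598081	449.6713
bird01_day00	a	2.625627	2.712778	561.3561
bird01_day00	b	2.733943	2.816748	680.3051
bird01_day00	c	2.838359	2.899363	835.0013
bird01_day00	d	2.926674	3.008276	973.2271
bird01_day00	a	3.033132	3.124841	548.0509
bird01_day00	b	3.151990	3.237247	710.3564
bird01_day00	c	3.259862	3.360040	865.8050
bird01_day00	d	3.409328	3.494557	998.5455
bird01_day00	i	4.555358	4.630864	447.7822
bird01_day00	a	4.692979	4.763877	539.2447
bird01_day00	b	4.839729	4.909382	697.9285
bird01_day00	c	4.953117	5.042115	840.9291
bird01_day00	d	5.070611	5.145003	1000.4326
bird01_day00	a	5.214074	5.293843	541.1437
bird01_day00	b	5.370045	5.445045	688.5362
bird01_day00	c	5.488769	5.554126	842.7451
bird01_day00	d	5.576507	5.671745	1007.7934
bird01_day00	i	6.504529	6.572228	444.0460
bird01_day00	a	6.651422	6.736118	552.7568
bird01_day00	b	6.804492	6.886156	705.5760
bird01_day00	c	6.908459	6.981568	833.0496
bird01_day00	d	7.047629	7.145709	1003.8472
bird01_day00	a	7.217205	7.286030	558.1175
bird01_day00	b	7.363549	7.430910	693.6622
bird01_day00	c	7.495084	7.574381	845.1860
bird01_day00	d	7.627683	7.698236	976.9187
bird01_day00	a	7.741221	7.839307	570.1275
bird01_day00	b	7.907812	7.989587	682.5170
bird01_day00	c	8.053896	8.135197	854.7690
bird01_day00	d	8.206389	8.283623	1020.6085
bird01_day00	i	9.299665	9.392161	439.9957
bird01_day00	i	9.464731	9.541687	453.1738
bird01_day00	i	9.593425	9.668362	456.0864
bird01_day00	i	9.741936	9.823032	451.3508
bird01_day00	a	9.889533	9.955730	554.0572
bird01_day00	b	10.009683	10.099467	714.2327
bird01_day00	c	10.132855	10.230424	825.1517
bird01_day00	d	10.296189	10.373241	1005.3252
bird01_day00	a	10.442712	10.530119	536.5565
bird01_day00	b	10.571273	10.647357	689.0773
bird01_day00	c	10.709440	10.791101	843.6587
bird01_day00	d	10.856498	10.939683	1007.5921
bird01_day00	i	11.976643	12.065168	455.7896
bird01_day00	i	12.120049	12.210350	448.3061
bird01_day00	a	12.264317	12.348985	537.9007
bird01_day00	b	12.419789	12.509902	725.6720
bird01_day00	c	12.575339	12.659246	861.6525
bird01_day00	d	12.688620	12.786992	1033.0731
bird01_day00	a	12.831444	12.896938	546.0578
bird01_day00	b	12.930501	13.010519	722.7435
bird01_day00	c	13.059043	13.142846	841.1097
bird01_day00	d	13.196286	13.270064	1004.8048
bird01_day00	i	14.703407	14.778635	454.5618
bird01_day00	a	14.839249	14.927886	548.1874
bird01_day00	b	14.973113	15.047897	696.0851
bird01_day00	c	15.091838	15.183802	849.5921
bird01_day00	d	15.246221	15.327296	1001.3092
bird01_day00	a	15.391158	15.470570	549.4757
bird01_day00	b	15.538690	15.618900	694.5857
bird01_day00	c	15.693562	15.775476	850.9955
bird01_day00	d	15.811580	15.890903	986.2497
bird01_day00	i	17.059762	17.145986	449.3097
bird01_day00	a	17.214182	17.291632	558.7355
bird01_day00	b	17.369119	17.439944	685.8898
bird01_day00	c	17.486044	17.565700	862.6841
bird01_day00	d	17.619806	17.698452	985.2882
bird01_day00	a	17.736597	17.827602	549.7711
bird01_day00	b	17.898455	17.985018	717.8809
bird01_day00	c	18.007465	18.096159	861.2915
bird01_day00	d	18.139596	18.228082	1025.7164
bird01_day00	i	19.494196	19.568146	450.8012
bird01_day00	i	19.600600	19.660274	455.2115
bird01_day00	a	19.687064	19.771931	558.1372
bird01_day00	b	19.834902	19.911264	700.8194
bird01_day00	c	19.969286	20.055117	854.3458
bird01_day00	d	20.105845	20.190164	978.8678
bird01_day00	a	20.242342	20.329742	541.7776
bird01_day00	b	20.365793	20.452952	708.4324
bird01_day00	c	20.527270	20.605833	852.7064
bird01_day00	d	20.629200	20.698464	966.3186
bird01_day00	i	21.680975	21.769753	454.8295
bird01_day00	a	21.805567	21.905832	551.4836
bird01_day00	b	21.965314	22.039795	713.8451
bird01_day00	c	22.082312	22.168741	854.9680
bird01_day00	d	22.231937	22.325200	979.9725
bird01_day00	a	22.396627	22.473291	536.7209
bird01_day00	b	22.509501	22.592205	690.8670
bird01_day00	c	22.668865	22.754506	887.3643
bird01_day00	d	22.823720	22.914220	993.6763
bird01_day00	a	22.974625	23.044792	549.6714
bird01_day00	b	23.108154	23.177961	700.4003
bird01_day00	c	23.225377	23.306469	863.2926
bird01_day00	d	23.350487	23.436177	990.3801
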