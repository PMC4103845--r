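snp	gene	chrom	pos	maf	minor_allele	major_allele
rs2072658	CHRNB2	1	154541323	0.175	T	A
rs2072659	CHRNB2	1	154542449	0.13	T	G
rs2072660	CHRNB2	1	154543911	0.131	T	C
rs2072661	CHRNB2	1	154545776	0.147	T	G
rs3811450	CHRNB2	1	154547321	0.158	T	G
rs10958726	CHRNB3	8	42551582	0.41	T	A
rs13277254	CHRNB3	8	42552677	0.41	A	G
rs13280604	CHRNB3	8	42553848	0.405	G	T
rs4950	CHRNB3	8	42555847	0.355	A	C
rs4952	CHRNB3	8	42557057	0.362	G	T
rs4953	CHRNB3	8	42557932	0.349	A	G
rs4954	CHRNB3	8	42559971	0.391	C	T
rs6474413	CHRNB3	8	42561936	0.398	A	C
rs2304297	CHRNA6	8	42612009	0.101	G	C
rs11633585	CHRNA5	15	78858576	0.32	A	C
rs11637635	CHRNA5	15	78860945	0.271	C	A
rs16969968	CHRNA5	15	78862214	0.291	T	A
rs17483686	CHRNA5	15	78863462	0.291	T	C
rs17486278	CHRNA5	15	78865402	0.303	G	C
rs2036527	CHRNA5	15	78866413	0.319	T	A
rs514743	CHRNA5	15	78867959	0.268	C	A
rs569207	CHRNA5	15	78869958	0.273	T	G
rs588765	CHRNA5	15	78872179	0.278	T	A
rs615470	CHRNA5	15	78873235	0.322	G	T
rs637137	CHRNA5	15	78875715	0.308	T	G
rs680244	CHRNA5	15	78878049	0.307	A	C
rs684513	CHRNA5	15	78879013	0.283	C	A
rs8034191	CHRNA5	15	78881277	0.297	G	C
rs905739	CHRNA5	15	78883263	0.265	T	C
rs951266	CHRNA5	15	78884621	0.329	A	T
rs1051730	CHRNA3	15	78886745	0.215	A	T
rs11637630	CHRNA3	15	78887954	0.218	G	T
rs12910984	CHRNA3	15	78890369	0.204	T	G
rs12914385	CHRNA3	15	78891554	0.245	T	A
rs1317286	CHRNA3	15	78893900	0.267	G	T
rs1878399	CHRNA3	15	78895287	0.269	T	C
rs3743074	CHRNA3	15	78896903	0.236	T	A
rs3743078	CHRNA3	15	78897802	0.236	T	G
rs578776	CHRNA3	15	78900189	0.216	G	A
rs6495308	CHRNA3	15	78901241	0.26	G	A
rs660652	CHRNA3	15	78903709	0.223	G	C
rs7177514	CHRNA3	15	78905256	0.2	A	G
rs11633223	CHRNB4	15	78918440	0.198	G	A
rs11636605	CHRNB4	15	78920238	0.243	T	A
rs12440014	CHRNB4	15	78922455	0.199	T	G
rs12914008	CHRNB4	15	78923554	0.205	C	G
rs1316971	CHRNB4	15	78924506	0.202	A	C
rs16970006	CHRNB4	15	78925383	0.245	A	G
rs17487223	CHRNB4	15	78927395	0.206	A	T
rs1948	CHRNB4	15	78929092	0.246	A	C
rs1996371	CHRNB4	15	78930575	0.211	T	A
rs3813567	CHRNB4	15	78931744	0.211	T	C
rs3971872	CHRNB4	15	78933568	0.235	C	A
rs7178270	CHRNB4	15	78934661	0.25	A	C
rs8023462	CHRNB4	15	78935938	0.256	C	T
rs950776	CHRNB4	15	78937237	0.209	C	A
rs2236196	CHRNA4	20	61976207	0.405	A	C
rs2273504	CHRNA4	20	61977529	0.418	A	C
rs3787116	CHRNA4	20	61978589	0.373	G	T
rs3787137	CHRNA4	20	61980763	0.378	T	G
rs6122429	CHRNA4	20	61981778	0.385	T	G
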