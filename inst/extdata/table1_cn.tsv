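case_id	contig	start	end	state
P2109_190	5	16715952	16736553	1
P2109_190	5	16758650	16771432	1
P72	7	70610154	72399292	1
P72	7	74050199	74834365	1
P2109_302	11	89843044	91294308	1
P2109_123	17	2173896	2414920	1
P2109_188	21	43427355	44858483	1
P2109_188	21	45803409	48095807	1
P81	4	155165258	158705411	1
P81	4	161300937	166372343	1
P81	4	171349346	174403566	1
P2046_133	5	144027815	146077337	1
P2046_133	5	146851376	149511942	1
P00	7	75063222	77310662	1
P00	7	77629679	77770664	1
P00	7	78236090	79911425	1
P00	7	82687283	82746799	1
P06	2	843845	1119040	3
P06	2	1611691	1857096	3
P4855_511	2	844930	1112989	3
P4855_511	2	1618416	1856851	3
P2109_150	7	111303881	114362948	3
P2109_151	14	102161711	102573503	3
P74	16	88727553	89319419	3
P74	16	89769750	90022565	3
P4855_512	21	43854701	44578748	3
P4855_512	21	44848406	46436410	3
P5513_206	14	47413346	47731287	3
P5513_206	14	49230279	60603652	3
P5513_206	14	63741627	75994279	3
P5513_206	14	86907487	87165260	3
P2109_162	1	238817623	244138230	1
P2109_162	1	245617207	246442209	1
P2109_162	1	247846701	248592414	3
P5513_116	X	285997	26552426	3
P5513_116	X	78198636	155559835	1
P5371_204	13	93528347	110077805	3
P5371_204	13	111492168	111972238	1
P5371_204	13	113582129	114985061	3
P2109_185	5	19524	2556252	1
P2109_185	5	2556253	21131828	3
P2109_185	5	177638723	180712342	3
P2109_176	2	186356601	188906835	1
P2109_176	2	188926928	225298653	3
P2109_176	2	225317517	226707110	1
P1426_301	21	16502517	26253075	1
P1426_301	21	27373586	27514060	3
P1426_301	21	28298721	28571261	3
P1426_301	21	29053919	29464120	1
P1426_301	21	31095940	31257111	3
P1426_301	21	33272142	36164839	1
P1426_301	21	38469325	38847524	1
P1426_301	21	46317441	46473088	3
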