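case_id	group	contig	accession	inheritance	pathogenicity	descriptor_raw	descriptor_norm	descriptor_alt
P2109_190	deletions_only	5	NC_000005.9	NA	VUS	NC_000005.9:g.[16715952_16736553del;16736554_ 16758649inv;16758650_16771432del]	NC_000005.9:g.[16715952_16736553del;16736554_16758649inv;16758650_16771432del]	NA
P72	deletions_only	7	NC_000007.14	dn	VUS	NC_000007.14:g.[70609300_72422999del;72423000_74047984inv;74047986_74049000del]	NC_000007.14:g.[70609300_72422999del;72423000_74047984inv;74047986_74049000del]	NA
P2109_302	deletions_only	11	NC_000011.9	mat	VUS	NC_000011.9:g.[89543002_89640782del;89640783_ 89766001inv;89766002_91339106del]	NC_000011.9:g.[89543002_89640782del;89640783_89766001inv;89766002_91339106del]	NA
P2109_123	deletions_only	17	NC_000017.10	pat	VUS	NC_000017.10:g.[2220422_2484969del;2484970_2617882inv;2617882_2649613del]	NC_000017.10:g.[2220422_2484969del;2484970_2617882inv;2617882_2649613del]	NA
P2109_188	deletions_only	21	NC_000021.8	dn	Pathogenic	NC_000021.8:g.[43414907_44797114del;44797115_44797221inv; 44797222_45781000del;45781001_45781001inv;45781002_ 48101999del]	NC_000021.8:g.[43414907_44797114del;44797115_44797221inv;44797222_45781000del;45781001_45781001inv;45781002_48101999del]	NA
P81	deletions_only	4	NC_000004.11	dn	Pathogenic	NC_000004.11:g.[154997276_155050346del;155164913_158707725del;158707726_171342995inv;161297891_166374443del;171342996_174401004del]	NC_000004.11:g.[154997276_155050346del;155164913_158707725del;158707726_171342995inv;161297891_166374443del;171342996_174401004del]	NA
P2046_133	deletions_only	5	NC_000005.9	dn	Likely Pathogenic	NC_000005.9:g.[389431_146087031delins[154993195_155919592];146087030_146847080inv;146847081_149533960;delins[143779195_144018754inv;141466787_143779194;399867_141466786inv;155929947_157385269];154977468_157385268del]	NC_000005.9:g.[389431_146087031delins154993195_155919592;146087030_146847080inv;146847081_149533960delins[143779195_144018754inv;141466787_143779194;399867_141466786inv;155929947_157385269];154977468_157385268del]	NA
P00	deletions_only	7	NC_000007.14	dn	Pathogenic	NC_000007.14:g.[74942506_77216338delins[77754229_77756619inv;77770732_78236952inv;78265840_82690202inv];77226982_77226980del;77226981_77626463inv;77626464_77626462del;77626463_78265840inv;78265841_82754313del]	NC_000007.14:g.[74942506_77216338delins[77754229_77756619inv;77770732_78236952inv;78265840_82690202inv];77226982_77226980del;77226981_77626463inv;77626464_77626462del;77626463_78265840inv;78265841_82754313del]	NA
P06	duplications_only	2	NC_000002.11	mat	VUS	NC_000002.11:g. [1114148_1114149ins[1610546_1855037;846167_1114148]] or NC_000002.11:g.[1855037_1855038ins[846167_1114148;1610546_1855037]]	NC_000002.11:g.[1114148_1114149ins[1610546_1855037;846167_1114148]]	NC_000002.11:g.[1855037_1855038ins[846167_1114148;1610546_1855037]]
P4855_511	duplications_only	2	NC_000002.11	mat	VUS	NC_000002.11:g.[1114148_1114149ins[1610546_1857566;842609_1114148]] or NC_000002.11:g.[1857566_1857567ins[842609_1114148;1610546_1857566]]	NC_000002.11:g.[1114148_1114149ins[1610546_1857566;842609_1114148]]	NC_000002.11:g.[1857566_1857567ins[842609_1114148;1610546_1857566]]
P2109_150	duplications_only	7	NC_000007.13	mat	VUS	NC_000007.13:g.[111941768_111941769ins[111963146_114365115;111281787_111941768]] or NC_000007.13:g.[114365115_114365116ins[111281787_111941768;111963146_114365115]]	NC_000007.13:g.[111941768_111941769ins[111963146_114365115;111281787_111941768]]	NC_000007.13:g.[114365115_114365116ins[111281787_111941768;111963146_114365115]]
P2109_151	duplications_only	14	NC_000014.8	mat	VUS	NC_000014.8:g.[105092354_105092355ins[102138899_102589089inv;104966644_105092354]]	NC_000014.8:g.[105092354_105092355ins[102138899_102589089inv;104966644_105092354]]	NA
P74	duplications_only	16	NC_000016.9	mat	Benign	NC_000016.9:g.[90023923_90023924ins[88726889_89324612inv;89772550_90023923]]	NC_000016.9:g.[90023923_90023924ins[88726889_89324612inv;89772550_90023923]]	NA
P4855_512	duplications_only	21	NC_000021.8	pat	VUS	NC_000021.8:g.[44845646_44846415_ins43854243_44581164inv;44844321_46454415dup]	NC_000021.8:g.[44845646_44846415ins43854243_44581164inv;44844321_46454415dup]	NA
P5513_206	duplications_only	14	NC_000014.8	dn	Likely Pathogenic	NC_000014.8:g.[61179000_61179001ins[47888602_48264000inv;49718081_59901890;87383926_87638698;64300950_76522298inv;59922753_61179000]]	NC_000014.8:g.[61179000_61179001ins[47888602_48264000inv;49718081_59901890;87383926_87638698;64300950_76522298inv;59922753_61179000]]	NA
P2109_162	deletions_and_duplications	1	NC_000001.11	dn	Likely Pathogenic	NC_000001.11:g.[238802166_244149898delins[246444835_246492103;247836549_248600189inv];244149899_246491796inv;245599009_246492102del]	NC_000001.11:g.[238802166_244149898delins[246444835_246492103;247836549_248600189inv];244149899_246491796inv;245599009_246492102del]	NA
P5513_116	deletions_and_duplications	X	NC_000023.10	dn	Likely Pathogenic	NC_000023.10:g.[77417096_qterdelins[76868256_77229642inv;pter_26552817inv]]	NC_000023.10:g.[77417096_qterdelins[76868256_77229642inv;pter_26552817inv]]	NA
P5371_204	deletions_and_duplications	13	NC_000013.10	dn	Pathogenic	NC_000013.10:g.[110081347_110102355delins93523111_110075934inv;111492500_111980567del;11358843_115000804dup]	NC_000013.10:g.[110081347_110102355delins93523111_110075934inv;111492500_111980567del;113588473_115000804dup]	NA
P2109_185	deletions_and_duplications	5	NC_000005.9	dn	Pathogenic	NC_000005.9:g.[pter_2559532delins[2587902_7481754inv;177636532_qterinv];7507897_7669625delins7673762_21097826inv]	NC_000005.9:g.[pter_2559532delins[2587902_7481754inv;177636532_qterinv];7507897_7669625delins7673762_21097826inv]	NA
P2109_176	deletions_and_duplications	2	NC_000002.11	dn	Pathogenic	NC_000002.11:g.[186345992_186383076delins187132941_186383235; 186383076_186383236inv;186383076_186383235ins[226652944_226738875inv;187132942_187298167];186383236_187298165del;188892330_225311353dup;225311194_226718660del]	NC_000002.11:g.[186345992_186383076delins187132941_186383235;186383076_186383236inv;186383076_186383235ins[226652944_226738875inv;187132942_187298167];186383236_187298165del;188892330_225311353dup;225311194_226718660del]	NA
P1426_301	deletions_and_duplications	21	NC_000021.8	dn	Pathogenic	NC_000021.8:g.[17867977_27624991_delins[29944106_29809107inv;29651577_29785938inv;32467984_32678337;?;28304789_28316917inv];?_?ins28727001_28879383;30426350_30815784delins30815785_34656669inv;34178763_34656669;34656670_37539019delins[47729066_47896585inv;45504605_46563358inv;37539020_40225591inv;46546718_46563358];39830240_40225590del]	NC_000021.8:g.[17867977_27624991delins[29944106_29809107inv;29651577_29785938inv;32467984_32678337;?;28304789_28316917inv];?_?ins28727001_28879383;30426350_30815784delins30815785_34656669inv;34178763_34656669;34656670_37539019delins[47729066_47896585inv;45504605_46563358inv;37539020_40225591inv;46546718_46563358];39830240_40225590del]	NA
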