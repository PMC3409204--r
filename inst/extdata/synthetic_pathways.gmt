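SYNTH_PATHWAY_01	synthetic gene set for examples	g0321	g1177	g1098	g1252	g1170	g0634	g0049	g1152	g1327	g0024
SYNTH_PATHWAY_02	synthetic gene set for examples	g0356	g1625	g0165	g0622	g1556	g0410	g1906	g1903	g0899	g1321	g0601	g1307	g0932	g0997	g0621	g1541
SYNTH_PATHWAY_03	synthetic gene set for examples	g1954	g0860	g1896	g0259	g1338	g0481	g1322	g0024	g1182	g0299	g1935	g0406	g0314
SYNTH_PATHWAY_04	synthetic gene set for examples	g1316	g0836	g0982	g0146	g1645	g1372	g0197	g1540	g0226	g0504	g1970	g1379	g0984	g0727	g0945	g1269	g0922
SYNTH_PATHWAY_05	synthetic gene set for examples	g0262	g0390	g0130	g1396	g1027	g0374	g1429	g0770	g1015	g1894	g0698
SYNTH_PATHWAY_06	synthetic gene set for examples	g0040	g0517	g0033	g0945	g0103	g1252	g0109	g1002	g1353	g1693	g0076	g0980	g1801	g1515	g1571	g0733	g0016	g1381	g1756
SYNTH_PATHWAY_07	synthetic gene set for examples	g1006	g1349	g0988	g1654	g1666	g0082	g1944	g1905	g0914	g0325	g1646	g1384	g0951	g0296	g0149	g0996	g1593
SYNTH_PATHWAY_08	synthetic gene set for examples	g0999	g0298	g0402	g0091	g0781	g1205	g1078	g0851	g0288	g0720	g1782	g0060	g1309
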