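chromosome	start	end	segVal	sample
c1	1	3054043	2	SYN001
c1	3054044	3232458	5	SYN001
c1	3232459	1e+07	2	SYN001
c2	1	29861	4	SYN001
c2	29862	388995	2	SYN001
c2	388996	656067	3	SYN001
c2	656068	682850	2	SYN001
c2	682851	1153030	3	SYN001
c2	1153031	3594098	3	SYN001
c2	3594099	4957204	1	SYN001
c2	4957205	5354246	1	SYN001
c2	5354247	6897227	1	SYN001
c2	6897228	1e+07	4	SYN001
c3	1	56340	3	SYN001
c3	56341	1e+07	1	SYN001
c4	1	805775	1	SYN001
c4	805776	1363171	4	SYN001
c4	1363172	1989549	3	SYN001
c4	1989550	5386140	3	SYN001
c4	5386141	9249638	3	SYN001
c4	9249639	1e+07	3	SYN001
c1	1	2311686	5	SYN002
c1	2311687	2329524	1	SYN002
c1	2329525	3053979	6	SYN002
c1	3053980	6497609	2	SYN002
c1	6497610	9163372	2	SYN002
c1	9163373	9165793	2	SYN002
c1	9165794	9278410	3	SYN002
c1	9278411	9611564	5	SYN002
c1	9611565	1e+07	2	SYN002
c2	1	605830	3	SYN002
c2	605831	2534866	3	SYN002
c2	2534867	7597904	2	SYN002
c2	7597905	1e+07	2	SYN002
c3	1	4291911	3	SYN002
c3	4291912	1e+07	4	SYN002
c4	1	6809737	2	SYN002
c4	6809738	1e+07	2	SYN002
c1	1	5290886	3	SYN003
c1	5290887	1e+07	3	SYN003
c2	1	1850207	1	SYN003
c2	1850208	3589460	3	SYN003
c2	3589461	3934359	2	SYN003
c2	3934360	5212708	2	SYN003
c2	5212709	7164332	7	SYN003
c2	7164333	8113816	2	SYN003
c2	8113817	8531032	2	SYN003
c2	8531033	9727829	3	SYN003
c2	9727830	1e+07	3	SYN003
c3	1	929909	3	SYN003
c3	929910	2206516	3	SYN003
c3	2206517	4688067	1	SYN003
c3	4688068	6331584	2	SYN003
c3	6331585	7477188	3	SYN003
c3	7477189	7596348	1	SYN003
c3	7596349	7671256	3	SYN003
c3	7671257	1e+07	2	SYN003
c4	1	2475590	1	SYN003
c4	2475591	4651875	2	SYN003
c4	4651876	5630534	2	SYN003
c4	5630535	6766357	5	SYN003
c4	6766358	7117557	2	SYN003
c4	7117558	7842879	2	SYN003
c4	7842880	8202743	3	SYN003
c4	8202744	8854777	2	SYN003
c4	8854778	9262610	4	SYN003
c4	9262611	1e+07	2	SYN003
c1	1	5976345	2	SYN004
c1	5976346	6027795	1	SYN004
c1	6027796	8469024	2	SYN004
c1	8469025	1e+07	3	SYN004
c2	1	8819600	2	SYN004
c2	8819601	1e+07	2	SYN004
c3	1	1200178	3	SYN004
c3	1200179	1722418	4	SYN004
c3	1722419	2950195	1	SYN004
c3	2950196	4533444	1	SYN004
c3	4533445	5879837	1	SYN004
c3	5879838	6402343	6	SYN004
c3	6402344	7705617	2	SYN004
c3	7705618	7902982	1	SYN004
c3	7902983	9752715	2	SYN004
c3	9752716	1e+07	1	SYN004
c4	1	1245532	1	SYN004
c4	1245533	1379231	3	SYN004
c4	1379232	1509851	2	SYN004
c4	1509852	1545120	3	SYN004
c4	1545121	1736270	1	SYN004
c4	1736271	3050851	2	SYN004
c4	3050852	5132544	2	SYN004
c4	5132545	5828791	3	SYN004
c4	5828792	7365837	1	SYN004
c4	7365838	9488871	2	SYN004
c4	9488872	9751757	2	SYN004
c4	9751758	1e+07	2	SYN004
c1	1	1914579	2	SYN005
c1	1914580	2095710	2	SYN005
c1	2095711	2766972	1	SYN005
c1	2766973	6345322	2	SYN005
c1	6345323	7181710	2	SYN005
c1	7181711	8395648	2	SYN005
c1	8395649	9932958	3	SYN005
c1	9932959	1e+07	5	SYN005
c2	1	7748771	3	SYN005
c2	7748772	1e+07	3	SYN005
c3	1	2178829	8	SYN005
c3	2178830	4315534	2	SYN005
c3	4315535	4947422	0	SYN005
c3	4947423	7029049	2	SYN005
c3	7029050	7407551	2	SYN005
c3	7407552	7942596	6	SYN005
c3	7942597	9351960	5	SYN005
c3	9351961	1e+07	4	SYN005
c4	1	3895857	2	SYN005
c4	3895858	8193231	3	SYN005
c4	8193232	1e+07	2	SYN005
c1	1	1715573	3	SYN006
c1	1715574	2795598	3	SYN006
c1	2795599	5728104	3	SYN006
c1	5728105	8617415	2	SYN006
c1	8617416	1e+07	6	SYN006
c2	1	212677	2	SYN006
c2	212678	1349604	1	SYN006
c2	1349605	2060429	4	SYN006
c2	2060430	3773771	3	SYN006
c2	3773772	4245650	3	SYN006
c2	4245651	5587342	8	SYN006
c2	5587343	6791706	2	SYN006
c2	6791707	7844353	2	SYN006
c2	7844354	1e+07	5	SYN006
c3	1	3641550	2	SYN006
c3	3641551	4387927	8	SYN006
c3	4387928	5627357	1	SYN006
c3	5627358	5662509	3	SYN006
c3	5662510	6275870	2	SYN006
c3	6275871	6807554	2	SYN006
c3	6807555	8984703	3	SYN006
c3	8984704	1e+07	4	SYN006
c4	1	3518078	3	SYN006
c4	3518079	3932647	2	SYN006
c4	3932648	5266360	3	SYN006
c4	5266361	6334293	2	SYN006
c4	6334294	7463379	2	SYN006
c4	7463380	7629217	4	SYN006
c4	7629218	7701707	2	SYN006
c4	7701708	8181390	3	SYN006
c4	8181391	8386047	1	SYN006
c4	8386048	8454808	2	SYN006
c4	8454809	9971962	2	SYN006
c4	9971963	1e+07	2	SYN006
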