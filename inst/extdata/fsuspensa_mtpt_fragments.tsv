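no	length	mismatches	gap_openings	cp_start	cp_end	mt_start	mt_end
1	3704	0	1	105768	109471	163780	160078
2	3179	0	2	34479	37657	490717	493893
3	2431	3	0	147015	149445	240258	237828
4	1730	26	12	13523	15249	195898	197601
5	1662	25	9	22086	23738	530312	531943
6	1406	0	0	143959	145364	222781	221376
7	735	11	4	80291	81024	472900	473621
8	1005	10	8	47478	48474	146737	147705
9	1365	18	7	51487	52821	412184	413485
10	433	11	2	16887	17318	286972	286547
11	676	5	5	66987	67651	89732	89092
12	349	1	0	76781	77129	340188	340536
13	389	14	5	96438	96810	358600	358212
14	674	7	12	69221	69878	231054	230418
15	885	18	6	103403	104266	305615	304757
16	149	2	0	145776	145924	240392	240244
17	163	15	2	32451	32611	146276	146114
18	90	2	1	105634	105723	465356	465269
19	85	3	1	111380	111463	6992	6908
20	80	5	0	54948	55027	268269	268348
21	47	0	0	58618	58664	340860	340814
22	32	0	0	114267	114298	91814	91845
23	90	16	3	9316	9404	146933	146846
24	31	0	0	90116	90146	480491	480461
25	30	0	0	103391	103420	317854	317825
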