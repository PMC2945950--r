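gene	s01	s02	s03	s04	s05	s06	s07	s08	s09	s10	s11	s12	s13	s14	s15	s16	s17	s18	s19	s20	s21	s22	s23	s24	s25	s26	s27	s28	s29	s30	s31	s32	s33	s34	s35	s36	s37	s38	s39	s40	s41	s42	s43	s44	s45	s46	s47	s48	s49	s50	s51	s52	s53	s54	s55	s56	s57	s58	s59	s60	s61	s62	s63	s64	s65
ADAP	0.3012	-0.0522	0.7019	-0.0086	0.415	0.9931	0.1464	-0.0047	0.0653	0.1805	0.3592	-0.8459	0.0122	0.8457	-0.0906	0.2268	-1.1029	-0.479	-1.1249	-1.7923	0.13	0.1132	-0.3582	-0.3667	0.6033	0.5393	0.9337	-0.8815	0.1344	-0.4084	-0.4733	-0.3791	0.7968	-0.4956	1.3667	-1.1608	-1.1581	0.5576	0.5067	-0.3515	-1.0478	0.1459	0.4866	0.7379	0.1142	-0.1081	1.2314	-0.895	0.1301	-0.1794	-0.6834	0.2508	-0.9816	0.8366	-0.0839	0.0579	1.3198	-0.0095	0.2429	-1.0436	-1.0771	-0.5296	0.8365	1.1555	-0.2168
GTP	-0.1673	-0.7738	-0.4334	0.2088	-0.9361	-0.8503	0.1269	-1.0402	-0.4613	-0.3017	-0.0408	0.5137	0.7704	0.4943	0.3707	0.3975	1.975	-1.1533	0.5394	1.6721	1.3515	1.0544	-0.05	-0.109	-1.0967	0.0153	-0.0053	0.9799	-0.2914	1.7819	-0.0915	0.0621	0.4684	0.8144	0.2308	1.0143	0.3079	-0.4388	-0.8054	1.1752	-0.5001	1.6179	-0.1465	1.5395	0.8479	0.4267	0.6421	0.5165	-0.8766	0.8178	-0.4132	0.528	-1.1223	0.5447	-0.6367	0.0052	-0.0391	-0.8001	-0.6688	0.4291	0.0868	-0.6973	0.5142	-1.4114	1.4741
KIN2	-0.196	0.8434	0.4307	0.9463	0.3445	1.7764	0.062	1.4054	-0.2263	-1.3218	0.2451	-0.4968	1.3444	1.0602	-0.8328	0.6656	-1.2182	-0.212	-0.964	0.243	-0.3754	-0.4366	-1.9516	-1.5993	-1.092	-1.0144	-0.3922	-0.1091	1.4525	-1.8245	-0.0822	1.067	0.2649	0.2071	0.4297	0.2279	-0.9607	-0.8785	-0.0389	0.4717	-0.8331	-0.7266	-0.0485	-0.6783	0.6487	-0.6746	-0.9708	-0.8053	1.0414	-0.4097	0.4182	-1.4039	-0.4535	-0.8831	-0.4773	0.5269	-0.1247	0.5069	-0.2514	0.5025	-0.1808	-1.0856	1.6761	0.7287	-1.8543
LIG	1.1109	0.1181	-0.6709	0.2506	-0.114	-0.1796	-0.6146	0.8574	-0.9985	-1.5849	2.0484	1.3926	0.1934	0.3991	0.6202	0.8574	0.4272	-0.0039	0.1682	-0.6638	-0.8165	1.638	-0.0756	1.4301	0.6483	0.3835	-0.6072	-0.3079	0.4546	0.9426	-0.8997	0.5807	-0.92	-0.0703	0.554	-0.1164	-0.9562	-0.0737	0.2225	0.6751	0.1604	-0.4675	-0.7998	0.5143	0.6289	-1.3027	1.4286	-1.2891	-0.8391	0.2855	0.2233	-1.905	-0.2057	-1.1126	0.8985	1.2283	-0.3949	-0.5049	1.124	0.9481	-1.162	-0.2108	-0.2175	0.663	-0.4503
MAPK	1.7842	0.0679	-0.2121	0.5698	-1.4662	0.0932	1.0294	1.6518	-0.5053	0.203	0.6108	-1.7811	0.4535	-0.2209	-1.5184	-1.2052	-0.761	-0.6516	-0.1267	-0.7612	0.6046	0.7245	0.2242	0.5013	-0.6099	0.846	-0.2296	-0.0902	0.7865	-1.6191	1.7834	-0.096	0.3267	-0.5866	1.6292	1.5558	1.6504	1.4866	-0.3267	-0.4674	1.3346	2.7168	1.2937	0.697	1.0788	1.2274	-0.1724	1.8881	0.6304	1.2144	0.6625	2.1465	0.7527	1.2593	0.6276	0.3523	1.1283	0.2604	-0.5622	-0.2202	0.7392	0.1885	0.0478	1.3245	0.0413
OUT	-0.9464	0.8246	1.0774	0.0535	0.1329	-1.0888	0.6092	-0.1817	-0.6467	0.6522	-0.149	0.657	-0.528	0.4179	-0.0857	-1.2082	1.6863	-0.584	0.3335	-0.948	-0.9076	-1.3494	-0.9787	1.145	0.4559	-0.5731	-0.6905	-0.0095	-1.1148	-1.4936	1.7507	-1.6919	1.0555	-0.3764	0.0913	-0.2791	0.8136	-0.2492	0.6173	-1.3934	-0.1945	0.5559	-1.3398	-0.4403	0.8832	0.5423	0.2006	-0.1917	0.9166	-0.3158	0.7611	-1.1105	-0.4293	-0.1834	0.1175	-0.8801	-0.4749	0.1685	-0.2908	0.6617	0.2868	0.4721	-0.3619	0.8825	-1.4131
PHOS	-1.1091	-1.0796	0.3165	2.0711	0.3314	-0.7895	0.4479	0.2218	1.186	-0.7	-0.2279	0.6593	0.3419	-0.2274	-0.7244	0.4484	-1.878	1.4357	-0.1107	0.1432	0.3004	0.1301	-0.1058	-1.3572	0.0385	-0.529	-0.7274	-0.4936	-0.1156	1.0761	-0.1166	0.8006	0.6657	0.2811	0.7084	0.9613	0.7254	-0.2085	-1.1635	-1.8164	0.5334	1.3683	0.3649	1.236	0.0046	0.411	-0.534	-0.4667	-1.2735	0.0098	-0.0767	1.3367	-0.4001	-0.6981	-1.2242	-0.75	0.3773	0.8443	-0.5837	-0.4904	-0.0521	-0.8961	-1.463	-1.2341	0.7403
RTK	-0.0209	-0.2921	0.6783	2.1406	-0.5903	-0.7047	0.2535	-0.4711	0.3837	-1.5465	0.6659	0.9631	0.5153	0.8144	0.723	0.2154	0.1636	0.5606	0.6661	-0.7652	0.2794	0.4434	-0.2201	0.1049	0.626	-0.285	0.0011	-0.3451	0.6895	0.0067	-1.2766	-0.5349	0.8304	-0.1744	-0.4444	1.1207	-0.0131	1.2406	1.2255	0.4873	0.3386	-0.143	0.0678	0.7995	0.2982	0.1869	0.8556	0.7199	-0.3239	1.2618	-0.3132	-0.5939	-0.7176	-1.7884	0.9567	0.3707	0.7029	-0.3276	-1.3953	-0.0685	0.2236	-0.5677	0.7827	-0.6923	-0.3512
SCAF	0.7068	0.6831	0.1994	-0.7794	-0.6056	-1.2399	0.7036	-0.4796	0.3024	0.2566	-0.1258	0.5931	-0.1668	-0.179	0.2215	0.1125	0.2845	-1.2483	-0.7118	0.4088	0.43	0.0374	0.1983	0.5544	-0.259	1.0781	0.0832	0.4608	0.0118	0.1177	-0.1254	-1.4464	-0.3574	0.3559	0.3738	0.6959	-0.2534	-0.2616	-0.0523	-1.1505	-0.0958	-0.4099	0.0237	0.5372	0.3253	0.8717	0.2083	-0.8484	-0.6546	0.2754	-0.8318	2.0218	-0.0747	-1.3911	-0.4633	-1.1639	1.8883	-0.5413	0.0318	-1.4369	-0.9195	-0.1914	-1.2854	-0.5399	-0.6609
TF1	-0.3662	-0.6417	0.9486	-0.2622	-0.2509	0.4512	0.3105	0.9782	0.3909	-0.1085	-0.1164	-0.8485	-0.1942	-0.1796	-0.1597	-0.8902	1.0006	0.612	1.0909	0.5391	-0.2372	0.009	0.3914	0.2885	1.1542	0.207	0.4296	0.8859	0.4501	0.1533	1.6285	0.1624	1.2806	-0.222	0.8913	1.0266	1.8104	0.9832	0.0648	1.397	1.131	-0.0775	0.4535	0.7503	0.7577	1.8561	0.7716	2.0842	-0.0467	0.9043	2.2023	0.4407	0.7037	0.2091	1.1459	0.5693	0.5611	0.4053	1.5974	-0.1527	-0.0135	0.2719	1.3959	1.9237	0.1163
KIN1a	0.2712	0.0949	-0.22	-0.3229	0.4483	0.4034	-0.916	-1.0658	-0.7468	0.4306	0.5183	0.1059	0.2747	0.3651	0.0601	-0.7079	-1.3541	-0.862	-1.4116	0.4978	-0.5464	1.7065	-0.3301	-0.3449	-1.9552	0.33	1.1783	-0.0339	0.6306	0.1006	0.3981	1.1909	1.2861	0.1696	0.1796	0.6376	0.0166	0.3167	-0.2874	2.6334	0.5404	1.2934	-0.9544	0.7534	0.4233	-0.2174	0.3605	-0.8706	-1.3758	0.2318	0.2185	-0.5976	0.6407	1.5755	0.3904	-1.2194	0.285	-0.0103	-0.5744	1.4575	-0.3289	-1.2823	0.0808	0.3174	0.3903
KIN1b	-0.3272	0.3776	-0.2976	-0.7127	0.7781	-0.1021	-0.5909	-0.5329	-0.7629	-0.3679	1.196	-0.284	-0.0165	-0.2691	0.4117	-0.5501	-1.5039	-1.5216	-0.9006	0.3762	-1.4806	1.6296	-0.7541	-0.597	-2.3507	-0.3557	0.9055	-0.1634	1.6677	-0.0036	-0.33	1.2493	1.196	-0.2052	0.6626	0.477	-0.0578	0.5469	0.0363	2.527	0.1293	0.6089	-1.5382	0.6605	0.2667	-0.5538	0.7176	-0.645	-0.8019	-0.0351	0.0475	-0.4092	1.303	1.7778	-0.1912	-0.7174	0.5838	-0.694	-0.1422	1.3006	-1.1555	-1.1103	1.4569	0.7934	0.4892
TF2a	0.5749	-2.0555	0.4417	-1.2014	1.2826	-0.5374	0.4282	-0.3079	-0.5716	0.3496	-0.3117	-0.0254	0.6958	-0.9271	-0.4525	-0.5875	0.2654	1.8128	0.4855	-0.7091	-0.9336	0.0522	0.3655	0.2835	-0.9272	0.1193	0.8751	1.2501	-0.7556	-0.2227	0.9826	-0.1748	-0.1623	-0.0099	0.6553	-1.5507	-2.5251	-0.6499	0.9228	-0.8072	1.2054	0.5471	-0.2025	-0.8223	0.2944	0.4429	0.3021	-0.4583	0.6261	0.3973	0.5715	-0.4732	0.2697	-0.5563	-0.0813	1.3538	0.0232	1.6408	0.3822	1.2217	-0.3371	1.1574	-0.5178	0.9965	-0.9746
TF2b	-0.0202	-2.0073	0.751	-0.7312	1.217	0.1421	1.2449	-1.0325	-0.9774	0.2531	-0.5556	0.1868	-0.3036	-1.417	-0.5207	-0.0862	0.1592	1.2917	0.5481	-0.3187	-0.6372	0.0626	0.2667	-0.213	-1.2875	-0.2395	0.3005	1.7097	-1.0083	0.3631	0.7716	-0.0977	-0.4878	0.2244	0.4256	-2.3945	-2.7113	-0.7784	1.0691	-0.3227	1.5518	0.6824	0.0155	-1.208	0.4537	0.3804	-0.0978	-0.0651	0.525	1.1069	0.5676	-0.7797	0.9751	-0.6939	-0.6219	1.2577	-0.0892	0.9464	0.249	0.9849	-0.6114	1.1911	-0.8803	0.3635	-1.1811
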