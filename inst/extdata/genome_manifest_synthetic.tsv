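genome_id	organism	exclusion_reason
IMG4207140	Methylobacterium sp. SYN1	
IMG5248728	Methylobacterium sp. SYN2	
IMG5818147	Methylobacterium sp. SYN3	
IMG4191935	Methylobacterium sp. SYN4	
IMG4061783	Methylobacterium sp. SYN5	
IMG5604259	Methylobacterium sp. SYN6	
IMG6828772	Methylobacterium sp. SYN7	
IMG8151123	Methylobacterium sp. SYN8	
IMG8218050	Methylobacterium sp. SYN9	
IMG3683480	Methylobacterium sp. CCH7-A2	classified as Bosea sp. by GTDB; IMG clique with Porphyrobacter donghaensis
IMG2737635	Methylobacterium sp. SYN11	
IMG8132676	Methylobacterium sp. SYN12	
IMG7008679	Methylobacterium sp. SYN13	
IMG1185657	Methylobacterium sp. SYN14	
IMG2547421	Methylobacterium sp. SYN15	
IMG3781070	Methylobacterium sp. SYN16	
IMG9910115	Methylobacterium sp. SYN17	
IMG5432853	Methylobacterium sp. SYN18	
IMG6986500	Methylobacterium sp. SYN19	
IMG1248033	Methylobacterium sp. SYN20	
IMG7433751	Methylobacterium sp. SYN21	
IMG8442693	Methylobacterium sp. SYN22	
IMG9728705	Methylobacterium sp. SYN23	
IMG8590914	Methylobacterium sp. SYN24	
IMG8683476	Methylobacterium sp. SYN25	
IMG1074742	Methylobacterium sp. SYN26	
IMG7650553	Methylobacterium sp. SYN27	
IMG1286752	Methylobacterium sp. SYN28	
IMG7614747	Methylobacterium sp. SYN29	
IMG5490203	Methylobacterium sp. SYN30	
IMG8708289	Methylobacterium sp. SYN31	
IMG6322647	Methylobacterium sp. SYN32	
IMG8365521	Methylobacterium sp. SYN33	
IMG5519533	Methylobacterium sp. SYN34	
IMG7798262	Methylobacterium sp. SYN35	
IMG3556052	Methylobacterium sp. SYN36	
IMG7517734	Methylobacterium sp. SYN37	
IMG3722193	Methylobacterium sp. SYN38	
IMG6921548	Methylobacterium sp. SYN39	
IMG6400863	Methylobacterium sp. SYN40	
IMG4892508	Methylobacterium sp. SYN41	
IMG6305963	Methylobacterium sp. SYN42	
IMG6544573	Methylobacterium sp. SYN43	
IMG5660508	Methylobacterium sp. SYN44	
IMG1005260	Methylobacterium sp. SYN45	
IMG3762281	Methylobacterium sp. SYN46	
IMG3708215	Methylobacterium sp. SYN47	
IMG7317306	Methylobacterium sp. SYN48	
IMG2574770	Methylobacterium sp. SYN49	
IMG6278957	Methylobacterium sp. SYN50	
IMG1864878	Methylobacterium sp. SYN51	
IMG1339447	Methylobacterium sp. SYN52	
IMG8348977	Methylobacterium sp. SYN53	
IMG3004897	Methylobacterium sp. SYN54	
IMG7145247	Methylobacterium sp. SYN55	
IMG1384213	Methylobacterium sp. SYN56	
IMG3441822	Methylobacterium sp. ZNC0032	annotated as Bosea sp.; does not cluster with Methylobacterium
IMG1376659	Methylobacterium sp. SYN58	
IMG3181545	Methylobacterium sp. SYN59	
IMG9326553	Methylobacterium sp. SYN60	
IMG3628800	Methylobacterium sp. SYN61	
IMG5307767	Methylobacterium sp. SYN62	
IMG2601883	Methylobacterium sp. SYN63	
IMG7975804	Methylobacterium sp. SYN64	
IMG3035610	Methylobacterium sp. SYN65	
IMG2792629	Methylobacterium sp. SYN66	
IMG3417801	Methylobacterium sp. SYN67	
IMG8351280	Methylobacterium sp. SYN68	
IMG1325154	Methylobacterium sp. SYN69	
IMG6100045	Methylobacterium sp. SYN70	
IMG7307556	Methylobacterium sp. SYN71	
IMG3018796	Methylobacterium sp. SYN72	
IMG3809523	Methylobacterium sp. SYN73	
IMG6279674	Methylobacterium sp. SYN74	
IMG2717789	Methylobacterium sp. SYN75	
IMG1821214	Methylobacterium sp. SYN76	
IMG9244347	Methylobacterium sp. SYN77	
IMG5098608	Methylobacterium sp. SYN78	
IMG4972723	Methylobacterium sp. SYN79	
IMG1008080	Methylobacterium sp. SYN80	
IMG1074398	Methylobacterium sp. SYN81	
IMG9860798	Methylobacterium sp. SYN82	
IMG1729792	Methylobacterium sp. SYN83	
IMG4607749	Methylobacterium sp. SYN84	
IMG1601030	Methylobacterium sp. SYN85	
IMG1179025	Methylobacterium sp. SYN86	
IMG2775355	Methylobacterium sp. SYN87	
IMG4672147	Methylobacterium platani JCM 14648 (duplicate entry)	second IMG entry for the same strain; earlier assembly used
IMG8689175	Methylobacterium sp. SYN89	
IMG7629546	Methylobacterium sp. SYN90	
IMG4479507	Methylobacterium sp. SYN91	
IMG4599925	Methylobacterium sp. SYN92	
IMG3778318	Methylobacterium sp. SYN93	
IMG6523361	Methylobacterium sp. SYN94	
IMG2140278	Methylobacterium sp. SYN95	
IMG8363610	Methylobacterium sp. SYN96	
IMG7097540	Methylobacterium sp. SYN97	
IMG6595027	Methylobacterium sp. SYN98	
IMG8465209	Methylobacterium sp. SYN99	
IMG7912456	Methylobacterium sp. SYN100	
IMG9319894	Methylobacterium sp. SYN101	
IMG6863538	Methylobacterium sp. SYN102	
IMG7858506	Methylobacterium sp. SYN103	
IMG4822192	Methylobacterium sp. SYN104	
IMG2907386	Methylobacterium sp. SYN105	
IMG4069032	Methylobacterium sp. SYN106	
IMG8423926	Methylobacterium sp. SYN107	
IMG9835469	Methylobacterium sp. SYN108	
IMG1784052	Methylobacterium sp. SYN109	
IMG4282441	Methylobacterium sp. SYN110	
IMG8898712	Methylobacterium sp. SYN111	
IMG3374337	Methylobacterium sp. SYN112	
IMG2763373	Methylobacterium sp. SYN113	
IMG2971034	Methylobacterium sp. SYN114	
IMG8826228	Methylobacterium sp. SYN115	
IMG2514405	Methylobacterium sp. SYN116	
IMG9042701	Methylobacterium sp. SYN117	
IMG6973792	Methylobacterium sp. SYN118	
IMG7080291	Methylobacterium sp. SYN119	
IMG3887519	Methylobacterium sp. SYN120	
IMG7650773	Methylobacterium sp. SYN121	
IMG8034628	Methylobacterium sp. SYN122	
IMG2901621	Methylobacterium sp. SYN123	
IMG1080411	Methylobacterium sp. SYN124	
IMG9551328	Methylobacterium sp. SYN125	
IMG8269340	Methylobacterium sp. SYN126	
IMG1554805	Methylobacterium sp. SYN127	
IMG8475163	Methylobacterium sp. SYN128	
IMG6334424	Methylobacterium sp. SYN129	
IMG8055561	Methylobacterium sp. SYN130	
IMG5738706	Methylobacterium sp. SYN131	
IMG6155885	Methylobacterium sp. SYN132	
IMG2249961	Methylobacterium sp. SYN133	
IMG7398934	Methylobacterium sp. SYN134	
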