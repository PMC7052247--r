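# vocal tract geometry (synthetic parametric stand-in unless replaced)
# q1_a=0.9
# q2_a=0.95
x	omega	phi1	phi2
0	1.4	1	1
0.175	1.40019737585371	0.999506560365732	0.998026728428272
0.35	1.40078930862869	0.998026728428272	0.992114701314478
0.525	1.40177521415877	0.99556196460308	0.982287250728689
0.7	1.40315411947421	0.992114701314478	0.968583161128631
0.875	1.40492466376194	0.987688340595138	0.951056516295154
1.05	1.40708509970852	0.982287250728689	0.929776485888251
1.225	1.4096332952245	0.975916761938747	0.90482705246602
1.4	1.41256673554855	0.968583161128631	0.876306680043864
1.575	1.41588252572922	0.960293685676943	0.844327925502015
1.75	1.41957739348194	0.951056516295154	0.809016994374947
1.925	1.42364769241831	0.940880768954225	0.770513242775789
2.1	1.4280894056447	0.929776485888251	0.728968627421412
2.275	1.43289814972641	0.917754625683981	0.684547105928689
2.45	1.43806917901359	0.90482705246602	0.63742398974869
2.625	1.44359739032465	0.891006524188368	0.587785252292473
2.8	1.44947732798245	0.876306680043864	0.535826794978997
2.975	1.45570318919842	0.860742027003944	0.481753674101715
3.15	1.46226882979919	0.844327925502015	0.425779291565073
3.325	1.46916777029018	0.827080574274562	0.368124552684678
3.5	1.47639320225002	0.809016994374947	0.309016994374947
3.675	1.48393799504972	0.79015501237569	0.248689887164855
3.85	1.49179470288968	0.770513242775789	0.187381314585725
4.025	1.49995557214782	0.75011106963046	0.125333233564304
4.2	1.50841254903144	0.728968627421412	0.0627905195293137
4.375	1.51715728752538	0.707106781186548	6.12323399573677e-17
4.55	1.52618115762852	0.684547105928689	-0.0627905195293132
4.725	1.53547525387054	0.661311865323652	-0.125333233564304
4.9	1.54503040410052	0.63742398974869	-0.187381314585724
5.075	1.55483717853881	0.612907053652977	-0.248689887164854
5.25	1.56488589908301	0.587785252292473	-0.309016994374947
5.425	1.57516664885915	0.562083377852131	-0.368124552684678
5.6	1.5856692820084	0.535826794978997	-0.425779291565073
5.775	1.59638343369985	0.509041415750371	-0.481753674101715
5.95	1.60729853035931	0.481753674101715	-0.535826794978996
6.125	1.61840380010418	0.453990499739547	-0.587785252292473
6.3	1.62968828337397	0.425779291565073	-0.637423989748689
6.475	1.64114084374609	0.397147890634781	-0.684547105928688
6.65	1.65275017892613	0.368124552684678	-0.728968627421411
6.825	1.66450483190188	0.338737920245292	-0.770513242775789
7	1.67639320225002	0.309016994374947	-0.809016994374947
7.175	1.68840355758431	0.278991106039229	-0.844327925502015
7.35	1.70052404513406	0.248689887164855	-0.876306680043863
7.525	1.71274270344138	0.218143241396543	-0.904827052466019
7.7	1.72504747416571	0.187381314585725	-0.929776485888251
7.875	1.73742621398391	0.156434465040231	-0.951056516295153
8.05	1.74986670657428	0.125333233564304	-0.968583161128631
8.225	1.76235667467259	0.0941083133185143	-0.982287250728689
8.4	1.77488379218827	0.0627905195293137	-0.992114701314478
8.575	1.78743569636875	0.0314107590781286	-0.998026728428272
8.75	1.8	6.12323399573677e-17	-1
8.925	1.81256430363125	-0.0314107590781281	-0.998026728428272
9.1	1.82511620781173	-0.0627905195293132	-0.992114701314478
9.275	1.83764332532741	-0.094108313318514	-0.982287250728689
9.45	1.85013329342572	-0.125333233564304	-0.968583161128631
9.625	1.86257378601609	-0.156434465040231	-0.951056516295154
9.8	1.87495252583429	-0.187381314585724	-0.929776485888252
9.975	1.88725729655862	-0.218143241396542	-0.90482705246602
10.15	1.89947595486594	-0.248689887164854	-0.876306680043864
10.325	1.91159644241569	-0.278991106039229	-0.844327925502015
10.5	1.92360679774998	-0.309016994374947	-0.809016994374948
10.675	1.93549516809812	-0.338737920245291	-0.77051324277579
10.85	1.94724982107387	-0.368124552684678	-0.728968627421412
11.025	1.95885915625391	-0.39714789063478	-0.684547105928689
11.2	1.97031171662603	-0.425779291565073	-0.63742398974869
11.375	1.98159619989582	-0.453990499739547	-0.587785252292473
11.55	1.99270146964069	-0.481753674101715	-0.535826794978997
11.725	2.00361656630015	-0.509041415750371	-0.481753674101715
11.9	2.0143307179916	-0.535826794978996	-0.425779291565073
12.075	2.02483335114085	-0.56208337785213	-0.368124552684679
12.25	2.03511410091699	-0.587785252292473	-0.309016994374948
12.425	2.04516282146119	-0.612907053652976	-0.248689887164855
12.6	2.05496959589948	-0.637423989748689	-0.187381314585725
12.775	2.06452474612946	-0.661311865323652	-0.125333233564305
12.95	2.07381884237148	-0.684547105928688	-0.0627905195293141
13.125	2.08284271247462	-0.707106781186547	-1.83697019872103e-16
13.3	2.09158745096856	-0.728968627421411	0.0627905195293128
13.475	2.10004442785218	-0.75011106963046	0.125333233564304
13.65	2.10820529711032	-0.770513242775789	0.187381314585723
13.825	2.11606200495028	-0.79015501237569	0.248689887164855
14	2.12360679774998	-0.809016994374947	0.309016994374947
14.175	2.13083222970982	-0.827080574274562	0.368124552684677
14.35	2.13773117020081	-0.844327925502015	0.425779291565073
14.525	2.14429681080158	-0.860742027003944	0.481753674101715
14.7	2.15052267201755	-0.876306680043863	0.535826794978996
14.875	2.15640260967535	-0.891006524188368	0.587785252292473
15.05	2.16193082098641	-0.904827052466019	0.637423989748689
15.225	2.16710185027359	-0.917754625683981	0.684547105928688
15.4	2.1719105943553	-0.929776485888251	0.728968627421411
15.575	2.17635230758169	-0.940880768954225	0.770513242775789
15.75	2.18042260651806	-0.951056516295153	0.809016994374947
15.925	2.18411747427078	-0.960293685676943	0.844327925502015
16.1	2.18743326445145	-0.968583161128631	0.876306680043863
16.275	2.1903667047755	-0.975916761938747	0.904827052466019
16.45	2.19291490029148	-0.982287250728689	0.929776485888251
16.625	2.19507533623806	-0.987688340595138	0.951056516295154
16.8	2.19684588052579	-0.992114701314478	0.968583161128631
16.975	2.19822478584123	-0.99556196460308	0.982287250728688
17.15	2.19921069137131	-0.998026728428272	0.992114701314478
17.325	2.19980262414629	-0.999506560365732	0.998026728428272
17.5	2.2	-1	1
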