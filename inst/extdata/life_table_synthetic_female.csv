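"age","mortality_rate"
0,0.000906
1,0.00090671107716387
2,0.00090750642611657
3,0.000908396034148866
4,0.000909391072173921
5,0.000910504035001777
6,0.000911748898238153
7,0.000913141293777784
8,0.000914698706095966
9,0.00091644069180318
10,0.000918389125219758
11,0.000920568473054311
12,0.000923006101635078
13,0.000925732620552142
14,0.00092878226702567
15,0.000932193335826732
16,0.000936008660149264
17,0.000940276149471549
18,0.00094504939116119
19,0.00095038832337802
20,0.000956359987724657
21,0.000963039371095825
22,0.000970510347297656
23,0.000978866730260977
24,0.000988213452073927
25,0.000998667880626582
26,0.00101036129341342
27,0.00102344052600033
28,0.00103806981585616
29,0.00105443286470201
30,0.00107273514527546
31,0.00109320648147599
32,0.00111610393429087
33,0.00114171502974033
34,0.00117036136937576
35,0.00120240266866839
36,0.00123824127399898
37,0.00127832721496882
38,0.00132316385547465
39,0.00137331421450854
40,0.00142940803605391
41,0.00149214969685513
42,0.00156232705135953
43,0.00164082132489875
44,0.00172861817933935
45,0.00182682009015535
46,0.00193666019034295
47,0.00205951775501733
48,0.00219693552113316
49,0.00235063905981482
50,0.00252255844455692
51,0.00271485248738513
52,0.00292993584731392
53,0.00317050935150501
54,0.0034395939098732
55,0.00374056844900901
56,0.00407721234175913
57,0.00445375286525774
58,0.00487491828334496
59,0.00534599721993447
60,0.00587290506888882
61,0.00646225827431908
62,0.0071214574140552
63,0.00785878012957621
64,0.00868348506933219
65,0.00960592815068675
66,0.0106376926003949
67,0.0117917344065497
68,0.013082545008456
69,0.0145263332673452
70,0.016141229002961
71,0.0179475106518481
72,0.0199678599060755
73,0.0222276465299235
74,0.0247552469310111
75,0.0275824004861992
76,0.0307446080966954
77,0.034281577977065
78,0.0382377242759726
79,0.0426627247898941
80,0.0476121447730762
81,0.0531481346769989
82,0.0593402105809377
83,0.0662661271135833
84,0.0740128538271018
85,0.0826776672840746
86,0.092369372570789
87,0.103209669575561
88,0.11533468118861
89,0.128896662613276
90,0.144065913252594
91,0.161032915179019
92,0.180010725040315
93,0.201237649437051
94,0.22498023736674
95,0.251536627311093
96,0.281240290996157
97,0.314464220836176
98,0.351625613643406
99,0.393191109417775
100,0.439682651000493
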