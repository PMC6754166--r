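"age","qx"
0,0.000511868950366812
1,0.000513170180028055
2,0.000514612579949114
3,0.000516211465437344
4,0.000517983813276279
5,0.000519948441956797
6,0.000522126211458196
7,0.000524540244696059
8,0.000527216172987899
9,0.000530182408138069
10,0.000533470444031847
11,0.000537115190932025
12,0.000541155346026501
13,0.000545633804154622
14,0.000550598113064349
15,0.000556100978027052
16,0.000562200821156322
17,0.000568962401355511
18,0.000576457501459848
19,0.000584765689849109
20,0.000593975164591809
21,0.00060418368905224
22,0.000615499628856875
23,0.000628043101182807
24,0.000641947248513408
25,0.000657359650313771
26,0.000674443887527576
27,0.000693381276398286
28,0.000714372789892503
29,0.000737641186961402
30,0.000763433372049982
31,0.000792023009658194
32,0.000823713421413075
33,0.000858840796037819
34,0.000897777745844874
35,0.000940937246949103
36,0.000988777004348074
37,0.00104180428736422
38,0.00110058128574764
39,0.00116573104202411
40,0.0012379440214999
41,0.00131798538774475
42,0.00140670305842028
43,0.00150503662406631
44,0.00161402722094905
45,0.00173482845838802
46,0.00186871851116599
47,0.00201711349876432
48,0.00218158228530918
49,0.00236386284733969
50,0.00256588037087324
51,0.00278976725479863
52,0.00303788521443493
53,0.0033128496971756
54,0.00361755684151566
55,0.00395521323143222
56,0.00432936871999479
57,0.00474395261916238
58,0.00520331357680015
59,0.00571226348683473
60,0.00627612580381531
61,0.00690078865854615
62,0.0075927631962972
63,0.00835924758261652
64,0.00920819714293508
65,0.0101484011196702
66,0.0111895665427219
67,0.0123424097140199
68,0.0136187558014575
69,0.0150316470188632
70,0.016595459832523
71,0.0183260315761713
72,0.02024079676917
73,0.022358933309358
74,0.0247015185437721
75,0.0272916949963056
76,0.0301548452385427
77,0.0333187750132623
78,0.0368139032416289
79,0.0406734569442426
80,0.0449336683592928
81,0.0496339706213371
82,0.0548171872420287
83,0.0605297092772734
84,0.066821652440057
85,0.0737469844905668
86,0.0813636109734996
87,0.0897334047503922
88,0.0989221617768413
89,0.108999462202429
90,0.120038412153647
91,0.132115237564888
92,0.145308697272397
93,0.159699278478533
94,0.175368133925584
95,0.192395717113393
96,0.210860070235722
97,0.230834719969228
98,0.252386139818492
99,0.27557074563116
100,0.300431404616858
101,0.326993459401382
102,0.355260299104762
103,0.385208550870862
104,0.416783019084817
105,0.449891566328552
106,0.484400209251872
107,0.520128791212503
108,0.556847686046776
109,0.594276074081689
110,1
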