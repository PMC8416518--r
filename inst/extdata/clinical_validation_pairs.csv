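respondent_id,calc_adaptive,calc_reactive,calc_creative,exp_adaptive,exp_reactive,exp_creative,similarity,disagreements
1,0.073,0.605,0.322,0.469,0.344,0.188,0.718,1
2,0.132,0.279,0.588,0.467,0.333,0.200,0.675,1
3,0.352,0.267,0.381,0.571,0.286,0.143,0.869,0
4,0.322,0.194,0.483,0.444,0.444,0.111,0.724,1
5,0.017,0.914,0.069,0.375,0.500,0.125,0.808,0
6,0.016,0.744,0.240,0.250,0.500,0.250,0.910,0
7,0.085,0.740,0.175,0.429,0.429,0.143,0.794,1
8,0.000,0.950,0.050,0.571,0.286,0.143,0.447,3
9,0.000,0.978,0.022,0.400,0.400,0.200,0.674,1
10,0.019,0.444,0.537,0.500,0.375,0.125,0.547,4
11,0.151,0.672,0.177,0.471,0.412,0.118,0.815,0
12,0.353,0.197,0.451,0.500,0.375,0.125,0.794,1
13,0.513,0.162,0.325,0.457,0.371,0.171,0.909,0
14,0.245,0.527,0.228,0.400,0.400,0.200,0.946,0
15,0.081,0.163,0.756,0.500,0.375,0.125,0.396,5
16,0.000,0.693,0.307,0.278,0.500,0.222,0.892,0
17,0.079,0.659,0.261,0.500,0.313,0.188,0.667,2
18,0.232,0.000,0.768,0.467,0.400,0.133,0.418,6
19,0.000,0.000,1.000,0.467,0.400,0.133,0.212,5
20,0.101,0.378,0.521,0.500,0.438,0.063,0.571,4
21,0.000,1.000,0.000,0.400,0.400,0.200,0.667,2
22,0.075,0.721,0.203,0.471,0.412,0.118,0.744,1
23,0.000,0.501,0.499,0.571,0.357,0.071,0.448,2
24,0.532,0.345,0.123,0.357,0.500,0.143,0.933,2
25,0.105,0.350,0.545,0.471,0.353,0.176,0.668,2
26,0.020,0.509,0.470,0.438,0.500,0.063,0.633,4
27,0.144,0.711,0.144,0.444,0.389,0.167,0.803,0
28,0.156,0.022,0.822,0.438,0.500,0.063,0.234,6
29,0.118,0.314,0.568,0.429,0.500,0.071,0.567,2
30,0.072,0.271,0.657,0.438,0.500,0.063,0.436,4
31,0.052,0.819,0.130,0.444,0.444,0.111,0.757,1
32,0.714,0.000,0.286,0.471,0.353,0.176,0.818,0
33,0.191,0.222,0.587,0.462,0.462,0.077,0.547,4
34,0.020,0.589,0.391,0.375,0.500,0.125,0.778,1
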