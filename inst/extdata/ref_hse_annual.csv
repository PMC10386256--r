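province,y2009,y2010,y2011,y2012,y2013,y2014,y2015,y2016,y2017,y2018,y2019,y2020,y2021,mean
Beijing,0.182,0.260,0.436,0.641,1.000,0.696,0.769,0.842,0.858,0.966,1.020,0.773,1.029,0.729
Tianjin,0.092,0.141,0.196,0.276,0.233,0.280,0.272,0.280,0.308,0.283,0.316,0.263,0.304,0.250
Hebei,0.233,0.422,0.439,0.463,0.280,0.490,0.482,0.510,0.496,0.500,0.515,0.489,0.492,0.447
Shanxi,0.099,0.144,0.175,0.207,0.128,0.223,0.227,0.234,0.244,0.246,0.256,0.240,0.260,0.206
Neimenggu,0.087,0.160,0.164,0.186,0.118,0.190,0.196,0.207,0.210,0.211,0.210,0.197,0.197,0.179
Liaoning,0.156,0.224,0.250,0.276,0.210,0.295,0.296,0.302,0.312,0.357,0.367,0.308,0.325,0.283
Jilin,0.096,0.142,0.158,0.180,0.123,0.196,0.221,0.228,0.243,0.241,0.255,0.231,0.249,0.197
Heilongjiang,0.127,0.185,0.204,0.217,0.166,0.224,0.234,0.248,0.279,0.288,0.284,0.194,0.201,0.219
Shanghai,0.246,0.337,0.528,0.587,1.014,0.656,0.599,0.768,0.836,0.958,1.002,0.890,1.036,0.728
Jiangsu,0.525,0.743,0.749,0.842,0.633,0.865,0.828,0.873,0.763,0.769,0.780,0.825,0.693,0.761
Zhejiang,0.409,0.581,0.719,0.785,0.622,0.842,0.806,0.858,0.862,0.885,1.013,0.881,1.007,0.790
Anhui,0.380,0.704,0.534,0.456,0.258,0.463,0.433,0.459,0.460,0.444,0.480,0.448,0.460,0.460
Fujian,0.341,0.437,0.394,0.405,0.246,0.414,0.404,0.424,0.465,0.505,0.517,0.484,0.526,0.428
Jiangxi,0.386,0.606,1.004,0.460,0.203,0.409,0.419,0.454,0.407,0.428,0.468,0.493,0.531,0.482
Shandong,0.342,0.576,0.619,0.604,0.400,0.613,0.687,0.711,0.688,0.651,0.627,0.654,0.616,0.599
Henan,0.475,0.745,0.768,0.734,0.488,0.819,0.829,1.001,0.867,0.887,0.910,0.899,0.969,0.799
Hubei,0.377,0.632,0.734,0.557,0.294,0.487,0.474,0.494,0.514,0.542,0.576,1.008,0.549,0.557
Hunan,0.301,0.579,0.600,0.531,0.301,0.534,0.462,0.535,0.566,0.558,0.576,0.517,0.536,0.507
Guangdong,0.609,0.929,0.845,1.040,0.757,1.005,0.938,0.959,0.933,1.001,1.019,0.958,1.026,0.925
Guangxi,0.470,0.840,1.016,1.019,1.010,0.950,0.887,0.865,0.837,0.851,1.025,0.807,0.728,0.870
Hainan,0.059,0.163,0.134,0.113,0.057,0.098,0.097,0.101,0.193,0.114,0.118,0.124,0.117,0.115
Chongqing,0.219,0.394,0.423,0.392,0.228,0.382,0.385,0.417,0.416,0.446,0.501,0.526,0.580,0.408
Sichuan,0.569,0.816,1.002,0.847,0.575,0.879,0.883,0.916,0.922,1.024,1.024,1.002,1.016,0.883
Guizhou,1.001,0.543,0.468,0.344,0.182,0.311,0.324,0.340,0.380,0.410,0.469,0.470,0.466,0.439
Yunnan,0.439,0.696,0.724,0.719,0.461,0.687,0.689,0.722,0.750,0.751,0.725,0.679,0.705,0.673
Xizang,0.016,0.022,0.028,0.040,0.016,0.033,0.028,0.033,0.033,0.035,0.040,0.044,0.046,0.032
Shaanxi,0.137,0.247,0.254,0.283,0.184,0.285,0.292,0.303,0.313,0.341,0.368,0.324,0.346,0.283
Gansu,0.094,0.161,0.176,0.168,0.100,0.195,0.190,0.196,0.200,0.194,0.193,0.186,0.192,0.173
Qinghai,0.024,0.042,0.040,0.046,0.030,0.046,0.050,0.051,0.055,0.063,0.060,0.063,0.067,0.049
Ningxia,0.036,0.066,0.066,0.069,0.046,0.070,0.072,0.080,0.079,0.084,0.089,0.084,0.088,0.071
Xinjiang,0.094,0.171,0.190,0.207,0.164,0.244,0.270,0.289,0.288,0.305,0.373,0.343,0.371,0.255
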