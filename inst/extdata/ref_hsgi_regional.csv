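transition,national_hsgi,national_ec,national_bpc,east_hsgi,east_ec,east_bpc,central_hsgi,central_ec,central_bpc,west_hsgi,west_ec,west_bpc
2009/2010,1.612,0.977,1.656,1.605,0.953,1.685,1.621,1.000,1.632,1.613,0.983,1.645
2010/2011,1.120,1.171,1.012,1.159,1.435,0.873,1.134,1.039,1.104,1.074,1.017,1.078
2011/2012,1.038,1.732,1.066,1.131,0.936,1.204,0.913,0.904,1.018,1.036,3.013,0.971
2012/2013,0.715,0.909,1.214,0.867,0.970,0.881,0.604,0.857,0.713,0.650,0.887,1.853
2013/2014,1.529,1.100,1.390,1.336,1.050,1.265,1.700,1.221,1.413,1.591,1.065,1.491
2014/2015,1.000,0.993,1.008,0.992,0.988,1.006,1.000,0.979,1.023,1.008,1.007,1.001
2015/2016,1.067,1.003,1.070,1.068,1.012,1.056,1.084,0.976,1.129,1.055,1.012,1.043
2016/2017,1.045,1.071,0.984,1.094,1.136,0.974,1.012,1.021,1.001,1.075,1.005,1.070
2017/2018,1.028,0.940,1.099,1.007,0.924,1.097,1.014,0.908,1.117,1.055,0.964,1.173
2018/2019,1.057,1.004,1.053,1.043,1.011,1.034,1.048,0.995,1.053,1.057,0.975,1.089
2019/2020,0.962,1.050,0.917,0.923,1.024,0.905,1.018,1.098,0.923,0.961,1.042,0.925
2020/2021,1.035,0.995,1.051,1.068,0.959,1.114,0.995,0.947,1.047,1.033,1.061,0.997
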