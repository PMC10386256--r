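province,region,hse_stage1,pte_stage1,se_stage1,hse_stage3,pte_stage3,se_stage3
Beijing,east,0.266,0.273,0.971,0.729,0.767,0.961
Tianjin,east,0.212,0.220,0.963,0.250,0.277,0.913
Hebei,east,0.708,0.747,0.943,0.447,0.463,0.962
Liaoning,east,0.319,0.333,0.955,0.283,0.308,0.920
Shanghai,east,0.400,0.812,0.520,0.728,0.929,0.778
Jiangsu,east,0.901,0.959,0.937,0.761,0.807,0.941
Zhejiang,east,0.690,0.799,0.874,0.790,0.865,0.907
Fujian,east,0.763,0.836,0.900,0.428,0.452,0.946
Shandong,east,0.774,0.854,0.900,0.599,0.615,0.972
Guangdong,east,0.968,0.997,0.971,0.925,0.953,0.971
Hainan,east,0.099,0.109,0.916,0.115,0.128,0.905
Shanxi,central,0.286,0.332,0.863,0.206,0.213,0.972
Jilin,central,0.189,0.202,0.936,0.197,0.207,0.953
Heilongjiang,central,0.206,0.213,0.962,0.219,0.234,0.941
Anhui,central,0.654,0.674,0.970,0.460,0.503,0.927
Jiangxi,central,0.582,0.595,0.976,0.482,0.573,0.869
Henan,central,0.683,0.705,0.969,0.799,0.844,0.946
Hubei,central,0.585,0.707,0.840,0.557,0.721,0.779
Hunan,central,0.454,0.486,0.940,0.507,0.541,0.941
Neimenggu,west,0.385,0.482,0.803,0.179,0.191,0.941
Guangxi,west,0.427,0.496,0.895,0.870,0.975,0.893
Chongqing,west,0.400,0.456,0.898,0.408,0.431,0.951
Sichuan,west,0.577,0.635,0.909,0.883,0.915,0.963
Guizhou,west,0.403,0.411,0.981,0.439,0.504,0.911
Yunnan,west,0.386,0.392,0.985,0.673,0.787,0.865
Xizang,west,0.038,0.142,0.577,0.032,0.130,0.608
Shaanxi,west,0.313,0.333,0.945,0.283,0.295,0.956
Gansu,west,0.308,0.392,0.891,0.173,0.181,0.952
Qinghai,west,0.071,0.085,0.868,0.049,0.053,0.932
Ningxia,west,0.237,0.265,0.900,0.071,0.078,0.921
Xinjiang,west,0.165,0.188,0.886,0.255,0.271,0.941
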