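# East/central/west partition of China's 31 provinces
# (National Bureau of Statistics classification; 11/8/12 split).
east:
  - Beijing
  - Tianjin
  - Hebei
  - Liaoning
  - Shanghai
  - Jiangsu
  - Zhejiang
  - Fujian
  - Shandong
  - Guangdong
  - Hainan
central:
  - Shanxi
  - Jilin
  - Heilongjiang
  - Anhui
  - Jiangxi
  - Henan
  - Hubei
  - Hunan
west:
  - Neimenggu
  - Guangxi
  - Chongqing
  - Sichuan
  - Guizhou
  - Yunnan
  - Xizang
  - Shaanxi
  - Gansu
  - Qinghai
  - Ningxia
  - Xinjiang
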