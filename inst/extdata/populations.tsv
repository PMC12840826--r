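# Five Hainan wild populations, ordered north to south (decreasing latitude).
name	latitude	longitude	locality
MY	18.94	109.51	Mao-Yang, Wuzhishan
TS	18.79	109.52	Tong-Shi, Wuzhishan
DA	18.47	108.90	Da-An, Ledong
TY	18.31	109.48	Tian-Ya, Sanya
JY	18.29	109.54	Ji-Yang, Sanya
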