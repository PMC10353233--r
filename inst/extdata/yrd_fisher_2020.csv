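region,Shanghai,Jiangsu,Zhejiang,Anhui
Shanghai,100,136.58,128.11,123.66
Jiangsu,73.22,100,93.43,88.27
Zhejiang,78.06,107.03,100,97.85
Anhui,80.86,113.29,102.20,100
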