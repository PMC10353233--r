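from,to,status
Shanghai,Jiangsu,inferred
Shanghai,Zhejiang,inferred
Zhejiang,Anhui,inferred
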