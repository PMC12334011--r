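state,X,C1,A,R,C2
X,0.902,0.070,0.026,,
C1,0.582,0.323,0.096,,
A,,,0.286,0.508,0.221
R,0.288,,0.108,0.477,0.127
C2,,,0.200,0.455,0.346
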