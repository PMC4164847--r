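node,i,j,score
A,B1,B2,1
A,B1,B3,1
A,B2,B3,1
C11,D1,D2,0
C11,D1,D3,0
C11,D1,D4,0
C11,D1,D5,0
C11,D2,D3,0
C11,D2,D4,0
C11,D2,D5,1
C11,D3,D4,0.5
C11,D3,D5,1
C11,D4,D5,1
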