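leaf,alternative,value
D1,road,0.66
D2,road,0.73
D3,road,0.62
D4,road,0.61
D5,road,0.53
D6,road,0.47
D7,road,0.35
D8,road,0.67
D9,road,0.36
D10,road,0.52
D11,road,0.68
D12,road,0.45
D13,road,0.89
D14,road,0
D15,road,0
D16,road,0
D17,road,0.56
D18,road,0.75
D19,road,0.074
D20,road,0.3
D21,road,0.1
D22,road,0.4
D23,road,0.63
D24,road,0.39
D25,road,0.56
D26,road,0.79
D27,road,0.16
D28,road,0.15
D29,road,0.67
D30,road,0.25
D31,road,0.27
D32,road,0.08
D33,road,0.78
D34,road,0
D35,road,0
D36,road,0.35
D37,road,0.37
D38,road,0.68
D39,road,0.56
D1,cableway,0.78
D2,cableway,0.76
D3,cableway,0.79
D4,cableway,0.65
D5,cableway,0.82
D6,cableway,0.58
D7,cableway,0.65
D8,cableway,0.71
D9,cableway,0.76
D10,cableway,0.57
D11,cableway,0.96
D12,cableway,0.95
D13,cableway,0.98
D14,cableway,1
D15,cableway,0.29
D16,cableway,1
D17,cableway,0.78
D18,cableway,0.89
D19,cableway,0.112
D20,cableway,0.35
D21,cableway,0.15
D22,cableway,0.4
D23,cableway,0.69
D24,cableway,0.44
D25,cableway,0.66
D26,cableway,0.87
D27,cableway,0.86
D28,cableway,0.89
D29,cableway,0.78
D30,cableway,0.53
D31,cableway,0.7
D32,cableway,0.13
D33,cableway,1
D34,cableway,0.1
D35,cableway,0.1
D36,cableway,0.89
D37,cableway,0.9
D38,cableway,0.76
D39,cableway,0.86
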