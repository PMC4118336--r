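area,operator,a,b
1,1,1.27,6.99
1,2,0.90,-93.82
1,3,0.89,416.4
2,1,-0.30,-155.94
2,2,-0.12,68.44
2,3,-0.14,11.99
3,1,2.08,84.70
3,2,2.44,80.60
3,3,1.00,-241.55
4,1,-1.07,-560.90
4,2,-0.41,158.36
4,3,-0.08,70.88
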