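u,v,operator,alpha,beta
300,180,1,56,107
300,180,2,60,105
300,180,3,58,109
180,-50,1,64,119
180,-50,2,64,120
180,-50,3,64,120
-300,-150,1,96,103
-300,-150,2,99,99
-300,-150,3,98,97
-200,180,1,91,82
-200,180,2,92,81
-200,180,3,88,84
-510,-180,1,111,85
-510,-180,2,111,82
-510,-180,3,110,84
510,360,1,52,94
510,360,2,52,97
510,360,3,54,94
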