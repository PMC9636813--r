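peak,NO_inhibition_vip,NO_inhibition_coef,compound
8,1.32,0.13,p-Coumaric acid
9,1.28,0.12,Luteolin-7-O-b-D-gentiobioside
13,1.31,0.13,Luteolin-7-O-b-D-glucoside
17,1.01,0.11,Isorhamnetin-3-O-b-D-glucoside
18,1.07,0.13,Luteolin
19,1.82,0.21,Kaempferol
20,1.31,0.16,Apigenin
21,1.53,0.17,Eupalitin
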