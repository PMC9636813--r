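compound_id,name,relative_content
5,Caffeic acid,4.2
7,Cichoric acid,60.0
8,p-Coumaric acid,1.1
18,Luteolin,2.4
19,Kaempferol,0.8
20,Apigenin,0.9
21,Eupalitin,0.7
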