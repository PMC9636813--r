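compound_id,name,smiles,mw,logp_mlogp,logp_wlogp,logp_xlogp,tpsa,hbd,hba,rotatable_bonds,molar_refractivity,heavy_atoms,rings,carbons,heteroatoms
5,Caffeic acid,O=C(O)/C=C/c1ccc(O)c(O)c1,180.16,1.20,1.20,1.20,77.76,3,3,2,46.44,13,1,9,4
7,Cichoric acid,O=C(/C=C/c1ccc(O)c(O)c1)OC(C(=O)O)C(OC(=O)/C=C/c1ccc(O)c(O)c1)C(=O)O,474.37,1.23,1.23,1.23,208.12,6,10,9,112.64,34,2,22,12
8,p-Coumaric acid,O=C(O)/C=C/c1ccc(O)cc1,164.16,1.49,1.49,1.49,57.53,2,2,2,44.78,12,1,9,3
18,Luteolin,O=c1cc(-c2ccc(O)c(O)c2)oc2cc(O)cc(O)c12,286.24,2.28,2.28,2.28,111.13,4,6,1,74.58,21,3,15,6
19,Kaempferol,O=c1c(O)c(-c2ccc(O)cc2)oc2cc(O)cc(O)c12,286.24,2.28,2.28,2.28,111.13,4,6,1,74.58,21,3,15,6
20,Apigenin,O=c1cc(-c2ccc(O)cc2)oc2cc(O)cc(O)c12,270.24,2.58,2.58,2.58,90.90,3,5,1,72.91,20,3,15,5
21,Eupalitin,COc1cc2oc(-c3ccc(O)cc3)c(O)c(=O)c2c(O)c1OC,330.29,2.59,2.59,2.59,109.36,3,7,3,86.02,24,3,17,7
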