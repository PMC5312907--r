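"id","name","smiles","conc","log_conc","log_conc_cal","split"
1,"N-Cyclohexyl-pyrrolidinone","O=C1CCCN1C1CCCCC1",3.5,0.544,0.317,"train"
2,"1,3-Dimethyltetrahydro-2(1H)-pyrimidinone","O=C1N(C)CCCN1C",0.65,-0.187,-0.617,"test"
3,"1-Butylpyrrolidin-2-one","CCCCN1CCCC1=O",0.279,-0.554,-0.48,"train"
4,"1-Benzylpyrrolidin-2-one","O=C1CCCN1Cc1ccccc1",0.18,-0.745,-0.566,"train"
5,"1-Methylpyrrolidin-2-one","CN1CCCC1=O",0.116,-0.935,-0.972,"test"
6,"3-(2-Oxo-1-pyrrolidinyl)propanenitrile","N#CCCN1CCCC1=O",0.115,-0.939,-0.51,"train"
7,"N-Ethyl-pyrrolidinone","CCN1CCCC1=O",0.101,-0.996,-1.2,"train"
8,"N-Octyl-pyrrolidone","CCCCCCCCN1CCCC1=O",0.092,-1.036,-1.241,"train"
9,"N-Vinyl-pyrrolidinone","C=CN1CCCC1=O",0.084,-1.076,-1.459,"train"
10,"Dimethyl-imidazolidinone","O=C1N(C)CCN1C",0.083,-1.08,-1.111,"train"
11,"Dimethylacetamide","CC(=O)N(C)C",0.041,-1.387,-1.534,"train"
12,"N-Formyl-piperidine","O=CN1CCCCC1",0.039,-1.409,-1.126,"test"
13,"N-Dodecyl-pyrrolidone","CCCCCCCCCCCCN1CCCC1=O",0.03,-1.553,-1.157,"train"
14,"Dimethylformamide","O=CN(C)C",0.023,-1.638,-2.374,"train"
15,"Benzyl acetate","CC(=O)OCc1ccccc1",0.0192,-1.717,-2.04,"train"
16,"Propionitrile","CCC#N",0.015,-1.824,-1.85,"train"
17,"Acrylic acid","C=CC(=O)O",0.0138,-1.86,-2.345,"train"
18,"2,2'-thiodiethanol","OCCSCCO",0.0136,-1.866,-2.1,"train"
19,"Ethanolamine","NCCO",0.0133,-1.876,-1.424,"test"
20,"Cyclopentanone","O=C1CCCC1",0.0129,-1.889,-1.757,"test"
21,"Chlorophenol","Oc1ccccc1Cl",0.012,-1.921,-2.064,"test"
22,"Acetone","CC(C)=O",0.011,-1.959,-1.53,"train"
23,"Benzyl benzoate","O=C(OCc1ccccc1)c1ccccc1",0.0109,-1.963,-2.16,"train"
24,"Isopropyl alcohol","CC(C)O",0.0105,-1.979,-2.038,"train"
25,"Cyclohexanone","O=C1CCCCC1",0.0068,-2.168,-2.33,"test"
26,"Toluene","Cc1ccccc1",0.005,-2.301,-2.056,"train"
27,"Triethyleneglycol","OCCOCCOCCO",0.0037,-2.432,-2.647,"train"
28,"Formamide","NC=O",3e-04,-3.523,-2.374,"train"
29,"Benzyl alcohol","OCc1ccccc1",0.000279,-3.554,-3.007,"train"
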