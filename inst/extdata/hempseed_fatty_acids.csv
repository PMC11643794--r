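peak,fatty_acid,class,percent,sd
1,"Myristic, C14:0",SFA,0.03,0.000
2,"Pentadecanoic, C15:0",SFA,0.01,0.001
3,"Palmitic, C16:0",SFA,6.50,0.014
4,"Palmitoleic, C16:1 c9",MUFA,0.10,0.001
5,"Eptadecanoic, C17:0",SFA,0.04,0.001
6,"Eptadecenoic, C17:1 c9",MUFA,0.02,0.001
7,"Stearic, C18:0",SFA,2.77,0.011
8,"Oleic, C18:1 c9",MUFA,13.12,0.010
9,"Octadecenoic, C18:1 c11",MUFA,1.02,0.035
10,"Linoleic, C18:2 n-6",PUFA,56.77,0.021
11,"Arachidic, C20:0",SFA,0.68,0.006
12,"gamma-Linolenic, C18:3 n-6",PUFA,1.83,0.022
13,"alpha-Linolenic, C18:3 n-3",PUFA,16.19,0.035
14,"Stearidonic, C18:4 n-3",PUFA,0.47,0.001
15,"Eicosadienoic, C20:2 n-6",PUFA,0.05,0.001
16,"Behenic, C22:0",SFA,0.29,0.003
17,"Lignoceric, C24:0",SFA,0.12,0.006
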