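species,n_specimens,diet,I,II,II/III,V,VI,VIII
Aeretes melanopterus,2,NoInfo,0,0,0,0,0,1
Aeromys tephromelas,4,Nucivore,1,0,0,0,0,0
Aeromys thomasi,1,Frugivore,1,0,0,0,0,0
Belomys pearsonii,2,Folivore_1,1,1,0,1,1,0
Biswamoyopterus laoensis,1,NoInfo,0,1,0,0,0,0
Eoglaucomys fimbriatus,8,Nucivore,0,0,1,1,0,1
Eupetaurus cinereus,1,Folivore_2,0,0,0,0,0,1
Glaucomys sabrinus,10,Nucivore,0,0,0,0,1,1
Hylopetes alboniger,7,Frugivore,1,1,0,1,0,1
Hylopetes bartelsi,1,NoInfo,1,0,0,0,0,0
Hylopetes nigripes,4,NoInfo,0,1,0,0,0,0
Hylopetes phayrei,6,Frugivore,1,1,0,0,0,0
Hylopetes platyurus,7,Generalist,1,0,0,0,0,0
Hylopetes sagitta,8,NoInfo,1,1,0,0,0,0
Hylopetes spadiceus,10,NoInfo,1,1,0,0,0,0
Iomys horsfieldii,1,Nucivore,1,0,0,0,0,0
Iomys sipora,1,NoInfo,1,0,0,0,0,0
Petaurillus kinlochii,4,NoInfo,1,0,0,0,0,0
Petaurista albiventer,1,Generalist,1,1,0,1,0,0
Petaurista alborufus,5,Generalist,1,1,0,1,1,0
Petaurista elegans,3,Generalist,1,1,0,1,0,1
Petaurista lena,3,Folivore_1,1,1,0,1,0,1
Petaurista leucogenys,6,Generalist,0,0,0,1,1,0
Petaurista petaurista,10,Folivore_1,1,1,0,1,0,1
Petaurista philippensis,5,Folivore_1,1,1,1,1,1,0
Petaurista yunanensis,5,NoInfo,1,1,0,1,1,1
Petinomys crinitus,3,NoInfo,1,1,0,0,0,0
Petinomys fuscocapillus,3,Generalist,1,1,0,0,0,0
Petinomys hageni,2,NoInfo,1,0,0,0,0,0
Petinomys lugens,4,NoInfo,1,0,0,0,0,0
Petinomys setosus,4,Nucivore,1,1,0,0,0,0
Petinomys vordermanni,6,Nucivore,1,0,0,0,0,0
Pteromys volans,6,Generalist,0,0,0,1,1,1
Pteromyscus pulverulentus,5,Generalist,1,0,0,1,0,0
Trogopterus xanthipes,2,Folivore_2,0,0,0,1,1,1
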