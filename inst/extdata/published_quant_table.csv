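species,condition,mass_ug,sd_ug,nmol,sd_nmol
Glc,LAM5_G9376,6.2,0.1,34.3,0.3
Glc,pretreated_G9376,3.4,0.1,18.9,0.5
LAM2,pretreated,2.5,0.1,7.4,0.2
LAM2,LAM5_G9376,4.0,0.1,11.8,0.1
LAM2,pretreated_G9376,4.1,0.1,12.1,0.1
X,pretreated_G9376,2.7,0.2,5.3,0.4
Hybrid,pretreated,7.7,0.1,5.9,0.05
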