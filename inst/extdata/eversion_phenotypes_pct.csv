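genotype,normal,weak,strong,early_lethal,n,p_printed
Ubx-GAL4_control,100.0,0.0,0.0,0.0,79,NA
Sce.IR-V27465_Ubx,49.1,2.7,32.1,16.1,112,<0.0001
Sce.IR-BL31612_Ubx,61.9,16.8,18.6,2.7,113,<0.0001
Sce.IR-V106328_Ubx,8.9,0.0,5.1,86.1,79,<0.0001
Sce.IR-V106328_odd,51.0,7.8,9.8,31.4,51,<0.0001
Sce.IR-V106328_puc,88.1,2.4,2.4,7.1,42,0.0043
Scm.IR-BL31614_Ubx,19.5,0.0,80.5,0.0,41,<0.0001
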