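genotype,normal,crumpled,cleft,single,double,lethal,n,p_printed
Sce.IR_alone,4.0,0.0,4.0,7.4,51.7,33.0,379,NA
Sce.IR_AbdB.IR-BL26746,42.8,0.0,28.3,4.9,4.0,19.9,346,<0.0001
Sce.IR_AbdB.IR-BL35647,47.1,9.1,3.8,6.8,10.6,22.7,397,<0.0001
Sce.IR_abdA.IR-BL28739,36.7,12.5,7.4,7.7,11.7,23.9,376,<0.0001
Sce.IR_abdA.IR-BL35644,37.0,9.5,4.1,7.8,17.3,24.3,243,<0.0001
Sce.IR_cad.IR-BL34702,29.3,5.2,13.1,9.3,26.6,16.6,290,<0.0001
Sce.IR_cad.IR-BL57546,30.8,0.5,10.0,5.0,26.9,26.9,201,<0.0001
Sce.IR_nub.IR-BL28338,11.8,1.8,5.9,5.9,41.2,33.5,272,0.0002
Sce.IR_nub.IR-BL56305,28.7,7.2,15.5,7.5,17.8,23.3,387,<0.0001
Sce.IR_GFP,4.8,0.0,17.6,9.1,42.4,26.1,165,0.6464
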