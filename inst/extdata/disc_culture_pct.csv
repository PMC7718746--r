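assay,genotype,percent,digits,n,p_printed
everted,control,57.5,1,80,NA
everted,Sce.IR,29.87,2,77,0.0007
aj_intact,control,9.1,1,66,NA
aj_intact,Sce.IR,52.0,1,50,0.0001
bm_intact,control,32.8,1,67,NA
bm_intact,Sce.IR,58.0,1,50,0.00845
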