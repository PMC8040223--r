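id,description,condition,a,b,c,d,sn_rs,sp_rs,e_check,n_check
mathews_hra,HRA cytology vs punch biopsy for high-grade squamous intraepithelial lesions in HIV patients,HSIL/ASC-H,40,22,22,177,0.74,0.91,62,261
matos_nc_lfpen,LFpen laser fluorescence vs visual inspection for non-cavitated occlusal caries (examiner 1),non-cavitated caries,241,6,110,26,0.796,0.799,351,383
matos_nc_fc,Fluorescence camera vs visual inspection for non-cavitated occlusal caries (examiner 1),non-cavitated caries,156,3,195,29,0.796,0.799,351,383
matos_d3_lfpen,LFpen laser fluorescence vs visual inspection for dentine caries (examiner 1),dentine caries,20,45,1,341,0.786,0.995,21,407
matos_d3_fc,Fluorescence camera vs visual inspection for dentine caries (examiner 1),dentine caries,21,38,0,348,0.786,0.995,21,407
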