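regulation,analyte,limit,unit
EPA biosolids CCL,cd,85,mg/kg
EPA biosolids CCL,cu,4300,mg/kg
EPA biosolids CCL,ni,420,mg/kg
EPA biosolids CCL,pb,840,mg/kg
EPA biosolids CCL,zn,7500,mg/kg
Austrian organic agriculture,cd,0.7,mg/kg
Austrian organic agriculture,cr,70,mg/kg
Austrian organic agriculture,cu,70,mg/kg
Austrian organic agriculture,ni,25,mg/kg
Austrian organic agriculture,pb,45,mg/kg
Austrian organic agriculture,zn,200,mg/kg
Austrian Class A agriculture,cd,1,mg/kg
Austrian Class A agriculture,cr,70,mg/kg
Austrian Class A agriculture,cu,150,mg/kg
Austrian Class A agriculture,ni,60,mg/kg
Austrian Class A agriculture,pb,120,mg/kg
Austrian Class A agriculture,zn,500,mg/kg
Austrian Class B land reclamation,cd,3,mg/kg
Austrian Class B land reclamation,cr,250,mg/kg
Austrian Class B land reclamation,cu,450,mg/kg
Austrian Class B land reclamation,ni,100,mg/kg
Austrian Class B land reclamation,pb,200,mg/kg
Austrian Class B land reclamation,zn,1500,mg/kg
EU organics,pah_total,6000,ug/kg
EU organics,pcddf_teq,100,ng/kg
Lower Austria organics,pcb_total,800,ug/kg
Lower Austria organics,pcddf_teq,100,ng/kg
EPA organics,pcb_total,200,ug/kg
EPA organics,pcddf_teq,300,ng/kg
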