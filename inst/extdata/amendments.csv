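"treatment_id","hht_celsius","available_n_mg_kg","p_g_kg","k_g_kg","ca_g_kg","mg_g_kg","s_mg_kg","micronutrients_mg_kg","cec_cations_g_kg","caco3_equiv_pct","bc100_pct","mass_yield","cd_mg_kg","cr_mg_kg","cu_mg_kg","ni_mg_kg","pb_mg_kg","zn_mg_kg","pah_total_ug_kg","pcb_total_ug_kg","pcddf_teq_ng_kg","h_total_frac","c_total_frac","c_inorg_frac"
"compost_60","60","429","1.44","2.93","5.12","1.37","171","355","9.56","4","2.7","0.501","0.43","23.6","42","18.3","50","280","56","1.96","0.97","0.03484306","0.25480022","0.00480022"
"torrefied_200","200","780","7.7","14.2","3.72","4.23","20","297","4.82","0.5","11.2","0.902","0.15","2.8","31","4.7","6.1","237","","","","0.06389597","0.50060003","0.00060003"
"pyrolyzed_300","300","26.3","6.65","15.1","2.86","4.04","176","138","9.43","2","44.1","0.54","0.23","12.1","76","11.9","4.4","374","942","0.91","0","0.04563317","0.55240011","0.00240011"
"pyrolyzed_400","400","11.6","7.18","17.3","3.26","4.32","220","171","7.94","4.9","60.5","0.474","0.27","5","72","9.1","4.7","470","","","","0.03516322","0.58588027","0.00588027"
"pyrolyzed_500","500","4.5","8.15","19.9","3.51","5.66","261","207","6.2","7.3","77.1","0.407","0.43","22.5","107","22.3","6.5","484","1633","1.22","0","0.02356658","0.62876041","0.00876041"
"pyrolyzed_600","600","2.1","9.17","21.8","2.8","6.43","298","237","3.75","5.6","85.2","0.341","0.22","5.9","395","8.6","3.5","591","","","","0.01753393","0.65672031","0.00672031"
"pyrolyzed_700","700","0.5","7.64","17.7","4.16","4.28","320","252","4.19","1","92.9","0.4","0.03","4","153","10.4","4.7","760","54","2.59","0","0.01120972","0.68120006","0.00120006"
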