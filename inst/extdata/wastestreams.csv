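community,population,fresh_g_per_person_day,water_content,dry_g_per_person_day,urine_ml_per_person_day
Nairobi,3375000,161.3,0.7,48.4,1000
Nairobi informal settlements,2193750,161.3,0.7,48.4,1000
Mukuru informal settlement,255094,161.3,0.7,48.4,1000
Sanergy latrine users 2015,54300,161.3,0.7,48.4,1000
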