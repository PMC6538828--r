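# hswvalue table schemas

All tables are comma-separated, UTF-8, "." decimal, one header row. Blank
cells are absent-value markers (NA), never zeros. Internal unit
convention: concentrations mg/kg dry amendment, CEC mmol_c/kg, prices USD
per kg of elemental component.

## amendments.csv

One row per treatment. Column names carry their unit; each quantity may be
supplied in exactly one of its accepted spellings.

| column (canonical) | alternatives | quantity |
|---|---|---|
| treatment_id | — | unique label (mandatory) |
| hht_celsius | — | highest heating temperature, degC; compost is tabulated at 60 (mandatory) |
| available_n_mg_kg | available_n_g_kg | NH4+-N + NO3−-N per kg amendment |
| p_mg_kg, k_mg_kg, ca_mg_kg, mg_mg_kg | *_g_kg | Mehlich-III extractable P, K, Ca, Mg |
| s_mg_kg, micronutrients_mg_kg | *_g_kg | Mehlich-III S and B+Cu+Mn+Zn |
| cec_mmolc_kg | — | cation exchange capacity |
| cec_cations_g_kg | cec_cations_mg_kg | retained K+ + Ca2+ + Mg2+ mass (the printed CEC row) |
| caco3_equiv_pct | — | CaCO3 equivalency, % w/w |
| h_total_frac, c_total_frac, c_inorg_frac | — | elemental mass fractions |
| bc100_pct | — | % of organic C persisting > 100 y |
| mass_yield | — | dry-mass fraction of feedstock recovered, (0, 1] |
| cd_mg_kg … zn_mg_kg | — | total acid-digestible Cd, Cr, Cu, Ni, Pb, Zn |
| pah_total_ug_kg, pcb_total_ug_kg | — | summed PAH / PCB |
| pcddf_teq_ng_kg | — | dioxin/furan TEQ |

## prices.csv

`component,price,unit,stratum,source`. `component` is one of
`available_n, p, k, ca, mg, s, micronutrients, caco3, co2`. Accepted
units: `USD/kg`, `USD/Mg`, `USD/t`, `USD/kg P2O5`, `USD/Mg P2O5`,
`USD/kg K2O`, `USD/Mg K2O`, `USD/kg CO2`, `USD/Mg CO2`. Oxide-basis
quotes are converted to the elemental basis by 0.4364 (P2O5 -> P) and
0.8301 (K2O -> K). `stratum` is `National` or `International`.

## benchmarks.csv

`name,n_total,p_total,k_total,market_price` — total N/P/K in kg per Mg of
product, market price in USD/Mg; one row per price observation, rows
sharing `name` form one benchmark.

## thresholds.csv

`regulation,analyte,limit,unit` — `analyte` uses the internal amendment
column names (`cd` … `zn`, `pah_total`, `pcb_total`, `pcddf_teq`); limits
in the internal unit for that analyte.

## tef.csv

`congener,tef` — toxic equivalency factors, dimensionless.

## wastestreams.csv

`community,population,fresh_g_per_person_day,water_content,dry_g_per_person_day,urine_ml_per_person_day`.
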