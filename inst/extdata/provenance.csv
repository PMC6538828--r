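field,treatment_id,raw_value,note
k,torrefied_200,1.42,"reconciled: the composition table renders available K at 200 degC as 1.42 g/kg, but the per-ton supply (14.2 kg available K per Mg) and the 0.65-fold statement against 600 degC (14.2/21.8) both require 14.2 g/kg; 14.2 is stored, the raw rendering is retained here"
available_n,torrefied_200,780,"the composition-table rendering of available N at 200 degC is ambiguous in some printings; the 371-fold statement against 600 degC (780/2.1) confirms 780 mg/kg"
mass_yield,,NA,"[DERIVED] dry-mass yields are not tabulated; values are a least-squares reconciliation of the printed fold-change and daily-mass statements (compost 26.4/52.7 = 0.501; 200 degC mean of 0.90 and 96/106.2 = 0.902; 300 degC from the 3.9x and 1.2x feedstock CEC folds = 0.540; 600 degC mean over the N 1002x, P 2.2x, K 1.7x, BC 2.9x folds and 36/106.2 = 0.341; 400/500 degC linear-in-HHT interpolation = 0.474/0.407; 700 degC 0.400 from the stated 60 percent maximum mass reduction). Override via an input file to use measured yields"
mass_yield,pyrolyzed_700,0.400,"[DERIVED] note: the 0.400 yield implied for 700 degC exceeds the 0.341 reconciled for 600 degC; the source statements are mutually inconsistent and both are retained as printed"
h_total,,NA,"[SYNTHETIC] elemental H is not tabulated; back-solved so the linear BC+100 model (-61.6 * H/C_org + 105) reproduces the tabulated BC+100 column exactly, given the synthetic C_org below"
c_total,,NA,"[SYNTHETIC] total C is not tabulated; organic C is set to literature-typical values for sawdust-amended HSW chars (0.25 compost rising to 0.68 at 700 degC) and inorganic C is derived from the CaCO3 equivalency (x 12.011/100.087)"
c_inorg,,NA,"[SYNTHETIC] derived from the CaCO3 equivalency; see c_total"
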