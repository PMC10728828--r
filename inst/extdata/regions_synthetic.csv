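region,cancer_cases_per_year,renewable_share,intensity_kg_per_kwh,forest_area_km2
Germany,552800,0.462,0.40,114190
United States,2380000,0.18,0.38,3100000
China,4568000,0.27,0.55,2200000
Japan,900000,0.19,0.46,249000
India,1200000,0.21,0.63,720000
Brazil,560000,0.83,0.10,4966000
United Kingdom,390000,0.37,0.23,31900
France,450000,0.21,0.06,172000
Rest of world,9625100,0.20,,29000000
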