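driver,scenario_label,year,value,rel_sd
renewables,planned,2023,0.20,0.05
renewables,planned,2030,0.30,0.06
renewables,planned,2040,0.44,0.08
renewables,planned,2050,0.55,0.10
renewables,below_2C,2023,0.20,0.05
renewables,below_2C,2030,0.38,0.06
renewables,below_2C,2040,0.65,0.08
renewables,below_2C,2050,0.86,0.10
model_complexity,mean,2023,1.0,0.05
model_complexity,mean,2032,20,0.30
model_complexity,mean,2042,400,0.45
model_complexity,mean,2052,8000,0.60
hardware_efficiency,mean,2023,1.0,0.03
hardware_efficiency,mean,2032,3.5,0.15
hardware_efficiency,mean,2042,12,0.25
hardware_efficiency,mean,2052,42,0.35
cases,mean,2023,1.00,0.02
cases,mean,2032,1.12,0.04
cases,mean,2042,1.26,0.06
cases,mean,2052,1.42,0.08
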