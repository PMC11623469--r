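indicator,subsystem,target_layer,attribute,unit_label
cod_emissions,EEC,EEC pressure,negative,tons / 1e8 yuan
so2_emissions,EEC,EEC pressure,negative,tons / 1e8 yuan
solid_waste_emissions,EEC,EEC pressure,negative,tons / 1e4 yuan
water_resources_pc,EEC,EEC state,positive,cubic meters
park_green_space_pc,EEC,EEC state,positive,square meters
green_coverage_rate,EEC,EEC state,positive,%
waste_treatment_rate,EEC,EEC response,positive,%
sewage_treatment_rate,EEC,EEC response,positive,%
green_finance,EEC,EEC response,positive,score
physicians_per_10k,RPH,Medical staff,positive,persons
nurses_per_10k,RPH,Medical staff,positive,persons
ph_managers_per_10k,RPH,Medical staff,positive,persons
primary_workers_per_10k,RPH,Medical staff,positive,persons
health_assets_pc,RPH,Medical facilities,positive,yuan
hospital_beds_per_1k,RPH,Medical facilities,positive,number
hospitals_per_10k,RPH,Medical facilities,positive,number
primary_inst_per_10k,RPH,Medical facilities,positive,number
maternal_mortality,RPH,Healing capacity,negative,per 1e5
perinatal_mortality,RPH,Healing capacity,negative,per 1e3
tertiary_hospitals,RPH,Healing capacity,positive,number
patients_per_physician,RPH,Medical efficiency,positive,number
bed_days_per_physician,RPH,Medical efficiency,positive,days
bed_utilization_rate,RPH,Medical efficiency,positive,%
avg_hospitalization_days,RPH,Medical efficiency,positive,days
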