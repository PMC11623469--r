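- indicator: cod_emissions
  subsystem: EEC
  target_layer: EEC pressure
  attribute: negative
  unit_label: tons / 1e8 yuan
- indicator: so2_emissions
  subsystem: EEC
  target_layer: EEC pressure
  attribute: negative
  unit_label: tons / 1e8 yuan
- indicator: solid_waste_emissions
  subsystem: EEC
  target_layer: EEC pressure
  attribute: negative
  unit_label: tons / 1e4 yuan
- indicator: water_resources_pc
  subsystem: EEC
  target_layer: EEC state
  attribute: positive
  unit_label: cubic meters
- indicator: park_green_space_pc
  subsystem: EEC
  target_layer: EEC state
  attribute: positive
  unit_label: square meters
- indicator: green_coverage_rate
  subsystem: EEC
  target_layer: EEC state
  attribute: positive
  unit_label: '%'
- indicator: waste_treatment_rate
  subsystem: EEC
  target_layer: EEC response
  attribute: positive
  unit_label: '%'
- indicator: sewage_treatment_rate
  subsystem: EEC
  target_layer: EEC response
  attribute: positive
  unit_label: '%'
- indicator: green_finance
  subsystem: EEC
  target_layer: EEC response
  attribute: positive
  unit_label: score
- indicator: physicians_per_10k
  subsystem: RPH
  target_layer: Medical staff
  attribute: positive
  unit_label: persons
- indicator: nurses_per_10k
  subsystem: RPH
  target_layer: Medical staff
  attribute: positive
  unit_label: persons
- indicator: ph_managers_per_10k
  subsystem: RPH
  target_layer: Medical staff
  attribute: positive
  unit_label: persons
- indicator: primary_workers_per_10k
  subsystem: RPH
  target_layer: Medical staff
  attribute: positive
  unit_label: persons
- indicator: health_assets_pc
  subsystem: RPH
  target_layer: Medical facilities
  attribute: positive
  unit_label: yuan
- indicator: hospital_beds_per_1k
  subsystem: RPH
  target_layer: Medical facilities
  attribute: positive
  unit_label: number
- indicator: hospitals_per_10k
  subsystem: RPH
  target_layer: Medical facilities
  attribute: positive
  unit_label: number
- indicator: primary_inst_per_10k
  subsystem: RPH
  target_layer: Medical facilities
  attribute: positive
  unit_label: number
- indicator: maternal_mortality
  subsystem: RPH
  target_layer: Healing capacity
  attribute: negative
  unit_label: per 1e5
- indicator: perinatal_mortality
  subsystem: RPH
  target_layer: Healing capacity
  attribute: negative
  unit_label: per 1e3
- indicator: tertiary_hospitals
  subsystem: RPH
  target_layer: Healing capacity
  attribute: positive
  unit_label: number
- indicator: patients_per_physician
  subsystem: RPH
  target_layer: Medical efficiency
  attribute: positive
  unit_label: number
- indicator: bed_days_per_physician
  subsystem: RPH
  target_layer: Medical efficiency
  attribute: positive
  unit_label: days
- indicator: bed_utilization_rate
  subsystem: RPH
  target_layer: Medical efficiency
  attribute: positive
  unit_label: '%'
- indicator: avg_hospitalization_days
  subsystem: RPH
  target_layer: Medical efficiency
  attribute: positive
  unit_label: days
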