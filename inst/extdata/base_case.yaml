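# Base-case model laboratory: averaged inputs of the seven modelled
# pathology departments. Fields not listed here (tariffs, capture ramps,
# workstation count, scanning-FTE profile, pathologist salary, equipment
# saving) are under-specified in the published material; they are defaulted
# on load, flagged "to be calibrated", and solved by calibrate_model()
# against the printed anchor set.
horizon: 7
discount_rate: 0.05
baseline_case_volume: 56000
natural_growth_rate: 0.0206
digitized_share: 0.814
slides_per_case: 4.5
productivity_gain: 0.074
baseline_consultations: 2785
consultation_growth_rate: 0.0206
scanner_unit_cost: 277000
initial_scanner_count: 5
scanner_capacity_increment: 75000
scanner_maintenance_annual: 65000
workstation_unit_cost: 4211
storage_it_initial: 278000
storage_it_annual: 155000
software_setup: 276000
software_annual_viewer: 73000
software_annual_casemgr_lis: 137000
technician_salary: 50000
fte_saved_pathologist: 0.20
fte_saved_technician: 0.80
tat_reduction: 0.153
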