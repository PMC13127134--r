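"quantity","value","units","source"
"population_2025",23126258,"persons","Results para 1"
"population_2040",24021710,"persons","Results para 1"
"population_growth_pct",3.9,"percent","Results para 1"
"frail_2025",16228687,"persons","Results para 2"
"frail_2040",18269340,"persons","Results para 2"
"frail_growth_pct",12.6,"percent","Results para 2"
"prevalence_2025_pct",70.2,"percent","Results para 2"
"prevalence_2040_pct",76.1,"percent","Results para 2"
"total_new_cases",10006500,"persons","Table 1 totals row"
"frail_cost_2025_million",45728.6,"pound millions","Table 3 row 2025"
"frail_cost_2040_million",55745.5,"pound millions","Table 3 row 2040"
"frail_cost_increase_billion",10,"pound billions","Abstract / Key points"
"total_cost_increase_billion",9.2,"pound billions","Discussion para 1"
"primary_frail_cost_rise_billion",1.6,"pound billions","Results para 3"
"secondary_frail_cost_rise_billion",8.4,"pound billions","Results para 3"
"scenario_a_frail_2040",18073867,"persons","Results, scenario A"
"scenario_a_frail_delta_2040",195473,"persons","Results, scenario A"
"scenario_a_gp_contacts_avoided_million",22,"contacts millions","Results, scenario A"
"scenario_a_secondary_contacts_avoided_million",11.5,"contacts millions","Results, scenario A"
"scenario_a_annual_saving_million",310,"pound millions","Results, scenario A"
"scenario_a_cumulative_saving_billion",4.97,"pound billions","Results, scenario A"
"scenario_b_modsev_2040_baseline",9390865,"persons","Results, scenario B"
"scenario_b_modsev_2040",9021522,"persons","Results, scenario B"
"scenario_b_modsev_delta_2040",369343,"persons","Results, scenario B"
"scenario_b_gp_contacts_avoided_million",19.5,"contacts millions","Results, scenario B"
"scenario_b_secondary_contacts_avoided_million",18.8,"contacts millions","Results, scenario B"
"scenario_b_annual_saving_million",644,"pound millions","Results, scenario B"
"scenario_b_cumulative_saving_billion",10.3,"pound billions","Results, scenario B"
"scenario_c_unplanned_admissions_avoided_million",2.48,"admissions millions","Results, scenario C"
"scenario_c_cumulative_saving_billion",4.2,"pound billions","Results, scenario C"
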