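method,cutting_area_code,working_quantity_ready,ready_cost,skidding_quantity_ready,skidding_cost,total_working_quantity,fuel_cost,equipment_depreciation,day_efficiency_m3_man,year_efficiency_m3_man,unit_cost
road,122-1-3,158,16.26,1161.2,119.47,1319.2,7.71,5,0.74,185.74,148.44
cableway,122-1-3,120,12.35,747.1,76.86,867.1,9.96,5.48,1.12,281.12,104.65
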