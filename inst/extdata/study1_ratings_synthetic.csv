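round,field,vignette,score
1,pressure_relief,1,0
1,pressure_relief,2,0
1,pressure_relief,3,3
1,pressure_relief,4,2
1,nutritional_management,1,0
1,nutritional_management,2,0
1,nutritional_management,3,0
1,nutritional_management,4,3
1,shear_relief,1,0
1,shear_relief,2,0
1,shear_relief,3,0
1,shear_relief,4,0
1,moisture_management,1,0
1,moisture_management,2,0
1,moisture_management,3,3
1,moisture_management,4,2
1,wound_dressing_use,1,0
1,wound_dressing_use,2,0
1,wound_dressing_use,3,0
1,wound_dressing_use,4,0
1,care_physical_factor,1,0
1,care_physical_factor,2,0
1,care_physical_factor,3,0
1,care_physical_factor,4,3
1,care_systemic_disorder,1,0
1,care_systemic_disorder,2,0
1,care_systemic_disorder,3,0
1,care_systemic_disorder,4,2
1,selection_dressings_ointments_npwt,1,0
1,selection_dressings_ointments_npwt,2,3
1,selection_dressings_ointments_npwt,3,3
1,selection_dressings_ointments_npwt,4,3
1,wound_cleansing,1,0
1,wound_cleansing,2,0
1,wound_cleansing,3,0
1,wound_cleansing,4,3
2,pressure_relief,1,0
2,pressure_relief,2,0
2,pressure_relief,3,0
2,pressure_relief,4,0
2,nutritional_management,1,0
2,nutritional_management,2,0
2,nutritional_management,3,0
2,nutritional_management,4,3
2,shear_relief,1,0
2,shear_relief,2,0
2,shear_relief,3,3
2,shear_relief,4,2
2,moisture_management,1,0
2,moisture_management,2,0
2,moisture_management,3,0
2,moisture_management,4,0
2,wound_dressing_use,1,0
2,wound_dressing_use,2,0
2,wound_dressing_use,3,0
2,wound_dressing_use,4,3
2,care_physical_factor,1,0
2,care_physical_factor,2,0
2,care_physical_factor,3,0
2,care_physical_factor,4,0
2,care_systemic_disorder,1,0
2,care_systemic_disorder,2,0
2,care_systemic_disorder,3,0
2,care_systemic_disorder,4,2
2,selection_dressings_ointments_npwt,1,0
2,selection_dressings_ointments_npwt,2,2
2,selection_dressings_ointments_npwt,3,2
2,selection_dressings_ointments_npwt,4,2
2,wound_cleansing,1,2
2,wound_cleansing,2,2
2,wound_cleansing,3,2
2,wound_cleansing,4,2
3,pressure_relief,1,0
3,pressure_relief,2,0
3,pressure_relief,3,0
3,pressure_relief,4,0
3,nutritional_management,1,0
3,nutritional_management,2,3
3,nutritional_management,3,3
3,nutritional_management,4,2
3,shear_relief,1,0
3,shear_relief,2,3
3,shear_relief,3,3
3,shear_relief,4,3
3,moisture_management,1,0
3,moisture_management,2,0
3,moisture_management,3,3
3,moisture_management,4,2
3,wound_dressing_use,1,0
3,wound_dressing_use,2,0
3,wound_dressing_use,3,0
3,wound_dressing_use,4,0
3,care_physical_factor,1,0
3,care_physical_factor,2,0
3,care_physical_factor,3,0
3,care_physical_factor,4,0
3,care_systemic_disorder,1,0
3,care_systemic_disorder,2,0
3,care_systemic_disorder,3,3
3,care_systemic_disorder,4,2
3,selection_dressings_ointments_npwt,1,3
3,selection_dressings_ointments_npwt,2,3
3,selection_dressings_ointments_npwt,3,3
3,selection_dressings_ointments_npwt,4,2
3,wound_cleansing,1,0
3,wound_cleansing,2,3
3,wound_cleansing,3,3
3,wound_cleansing,4,3
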