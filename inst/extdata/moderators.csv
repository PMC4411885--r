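parameter,level_label,filter_column,filter_value,n_mz_unique,n_dz_unique,r_mz_printed,r_dz_printed
instrument,yes,uses_instrument,TRUE,2951,2280,0.62,0.51
instrument,no,uses_instrument,FALSE,2864,2143,0.63,0.40
informant,twins,informant,twins,5005,3844,0.60,0.46
informant,third_person,informant,third_person,810,579,0.75,0.42
sample_size_split,below_median,size_group,below,910,831,0.51,0.31
sample_size_split,above_median,size_group,above,4460,3101,0.66,0.51
interview_age,proximate_le19,interview_age_band,proximate_le19,1786,1536,0.73,0.51
interview_age,distant_gt22,interview_age_band,distant_gt22,3404,2396,0.56,0.41
gender,male,gender,male,502,498,0.56,0.31
gender,female,gender,female,660,544,0.55,0.38
site,us_canada,site,us_canada,2583,1892,0.56,0.41
site,europe_australia,site,europe_australia,2607,2040,0.70,0.50
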