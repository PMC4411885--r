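study_id,label,n_mz_pairs,n_dz_pairs,site,informant,interview_age_band,country
erisk,"E-Risk study (Ball 2008; Jaffee 2004)",625,491,europe_australia,third_person,proximate_le19,UK
shakoor,"Shakoor 2011",709,629,europe_australia,twins,proximate_le19,UK
bornovalova,"Bornovalova 2013",896,486,us_canada,twins,distant_gt22,US
dinwiddie,"Dinwiddie 2000",923,525,europe_australia,twins,distant_gt22,Australia
schulz_heik,"Schulz-Heik 2010",271,397,us_canada,twins,distant_gt22,US
lau_eley,"Lau and Eley 2008",267,328,europe_australia,twins,proximate_le19,UK
rooks,"Rooks 2012",146,95,us_canada,twins,distant_gt22,US
silberg,"Silberg 2005",185,88,us_canada,third_person,proximate_le19,US
stein,"Stein 2002",222,184,us_canada,twins,distant_gt22,Canada
vinkhuyzen,"Vinkhuyzen 2011",83,67,europe_australia,twins,distant_gt22,Netherlands
young_wolff,"Young-Wolff 2011",860,642,us_canada,twins,distant_gt22,US
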