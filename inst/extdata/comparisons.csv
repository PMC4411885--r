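comparison_id,study_id,construct,stratum_label,r_mz,r_dz,n_mz_eff,n_dz_eff,gender,uses_instrument,informant,site,interview_age_band,size_group,measure_description
erisk_bully_boys,erisk,bullying,boys,0.77,0.41,625,491,male,FALSE,third_person,europe_australia,proximate_le19,above,"Parent report: single question on bullying by another child since age 5"
erisk_bully_girls,erisk,bullying,girls,0.65,0.36,625,491,female,FALSE,third_person,europe_australia,proximate_le19,above,"Parent report: single question on bullying by another child since age 5"
shakoor_bully,shakoor,bullying,all,0.62,0.42,709,629,mixed,TRUE,twins,europe_australia,proximate_le19,above,"Multidimensional Peer Victimization Scale, 16-item total score"
vinkhuyzen_bully_primary,vinkhuyzen,bullying,primary school,0.74,0.41,83,67,mixed,TRUE,twins,europe_australia,distant_gt22,below,"Item on being bullied at primary school"
vinkhuyzen_bully_secondary,vinkhuyzen,bullying,secondary school,0.52,0.23,83,67,mixed,TRUE,twins,europe_australia,distant_gt22,below,"Item on being bullied at secondary school"
bornovalova_sexual,bornovalova,sexual_abuse,all,0.60,0.58,896,486,mixed,TRUE,twins,us_canada,distant_gt22,above,"Trauma Assessment for Adults and Childhood Experiences Questionnaire sexual-abuse items"
dinwiddie_sexual,dinwiddie,sexual_abuse,all,0.68,0.52,923,525,mixed,FALSE,twins,europe_australia,distant_gt22,above,"Single item: forced into sexual activity before age 18"
bornovalova_physical,bornovalova,physical_maltreatment,all,0.61,0.56,896,486,mixed,TRUE,twins,us_canada,distant_gt22,above,"Four CEQ items on physical abuse and harsh discipline"
erisk_maltreatment,erisk,physical_maltreatment,maltreatment,0.77,0.71,625,491,mixed,TRUE,twins,europe_australia,proximate_le19,above,"Clinical interview protocol (Multi-Site Child Development project), physical maltreatment probes"
erisk_punishment,erisk,physical_maltreatment,corporal punishment,0.90,0.79,625,491,mixed,TRUE,twins,europe_australia,proximate_le19,above,"Clinical interview protocol (Multi-Site Child Development project), corporal punishment probes"
schulz_physical_males,schulz_heik,physical_maltreatment,males,0.33,0.03,271,397,male,FALSE,twins,us_canada,distant_gt22,below,"Single question: slapped hit or kicked by parents or adult caregivers"
schulz_physical_females,schulz_heik,physical_maltreatment,females,0.55,0.56,271,397,female,FALSE,twins,us_canada,distant_gt22,below,"Single question: slapped hit or kicked by parents or adult caregivers"
schulz_emotional_males,schulz_heik,emotional_abuse_neglect,males,0.31,0.28,271,397,male,FALSE,twins,us_canada,distant_gt22,below,"Two questions on being left alone and neglect of basic needs"
schulz_emotional_females,schulz_heik,emotional_abuse_neglect,females,0.41,0.20,271,397,female,FALSE,twins,us_canada,distant_gt22,below,"Two questions on being left alone and neglect of basic needs"
bornovalova_emotional,bornovalova,emotional_abuse_neglect,all,0.53,0.36,896,486,mixed,TRUE,twins,us_canada,distant_gt22,above,"Six CEQ items on emotional abuse"
young_wolff_combined,young_wolff,combined_abuse,all,0.64,0.57,860,642,mixed,FALSE,twins,us_canada,distant_gt22,above,"Combined score from three questions on physical abuse sexual abuse and neglect"
silberg_events_t1,silberg,general_trauma,first time point,0.91,0.75,185,88,mixed,FALSE,third_person,us_canada,proximate_le19,below,"Mother report: subset of 39 past-year negative life events"
silberg_events_t2,silberg,general_trauma,1.5 years later,0.89,0.52,185,88,mixed,FALSE,third_person,us_canada,proximate_le19,below,"Mother report: subset of 39 past-year negative life events"
stein_assaultive,stein,general_trauma,assaultive,0.43,0.28,222,184,mixed,TRUE,twins,us_canada,distant_gt22,below,"Traumatic Event Questionnaire, assaultive trauma items"
stein_nonassaultive,stein,general_trauma,non-assaultive,0.39,0.25,222,184,mixed,TRUE,twins,us_canada,distant_gt22,below,"Traumatic Event Questionnaire, non-assaultive trauma items"
lau_events_males,lau_eley,general_trauma,males,0.57,0.42,267,328,male,TRUE,twins,europe_australia,proximate_le19,above,"Life Events Scale for Adolescents, 12 twin-specific negative events"
lau_events_females,lau_eley,general_trauma,females,0.50,0.41,267,328,female,TRUE,twins,europe_australia,proximate_le19,above,"Life Events Scale for Adolescents, 12 twin-specific negative events"
vinkhuyzen_events,vinkhuyzen,general_trauma,all,0.50,0.44,83,67,mixed,TRUE,twins,europe_australia,distant_gt22,below,"List of Threatening Experiences, summed negative life events"
rooks_trauma,rooks,general_trauma,all,0.54,0.47,146,95,mixed,TRUE,twins,us_canada,distant_gt22,below,"Early Trauma Inventory total score, dichotomized"
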