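construct,member_comparison_ids,n_mz_unique,n_dz_unique
bullying,erisk_bully_boys;erisk_bully_girls;shakoor_bully;vinkhuyzen_bully_primary;vinkhuyzen_bully_secondary,1417,1187
sexual_abuse,bornovalova_sexual;dinwiddie_sexual,1749,1011
physical_maltreatment,bornovalova_physical;erisk_maltreatment;erisk_punishment;schulz_physical_males;schulz_physical_females,1792,1374
emotional_abuse_neglect,schulz_emotional_males;schulz_emotional_females;bornovalova_emotional,1167,883
general_trauma,silberg_events_t1;silberg_events_t2;stein_assaultive;stein_nonassaultive;lau_events_males;lau_events_females;vinkhuyzen_events;rooks_trauma,903,762
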